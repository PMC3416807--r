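toy_vectors <- function() {
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  m
}

test_that("vectorization uses the mask scan order and inverts cleanly", {
  g <- toy_mask(8, 2)
  g$mask[1:10] <- FALSE
  v1 <- array(rnorm(64), dim(g$values))
  v2 <- array(rnorm(64), dim(g$values))
  maps <- list(m1 = volume_map(v1, g$voxel_size, g$origin, g$mask),
               m2 = volume_map(v2, g$voxel_size, g$origin, g$mask))
  vec <- vectorize_maps(maps)
  expect_equal(dim(vec), c(2, sum(g$mask)))
  expect_equal(rownames(vec), c("m1", "m2"))
  expect_equal(vectorize_maps(list(a = maps$m1, b = maps$m1))[1, ],
               vectorize_maps(list(a = maps$m1, b = maps$m1))[2, ])
  back <- devectorize_map(vec[1, ], maps$m1)
  expect_equal(back$values, maps$m1$values)
})

test_that("distance matrix is 1 - Pearson r with hand-checked values", {
  m <- toy_vectors()
  D <- distance_matrix(m)
  expect_equal(D["a", "b"], 0, tolerance = 1e-12)        # perfectly correlated
  expect_equal(D["a", "c"], 2, tolerance = 1e-12)        # perfectly anti
  r_ac <- cov(m["a", ], m["c", ]) / (sd(m["a", ]) * sd(m["c", ]))
  expect_equal(D["a", "c"], 1 - r_ac, tolerance = 1e-12)
  expect_equal(diag(D), c(a = 0, b = 0, c = 0))
  expect_equal(unclass(D), t(unclass(D)))

  bad <- rbind(flat = c(1, 1, 1, 1), ok = c(1, 2, 3, 4))
  expect_error(distance_matrix(bad), "flat")
})

test_that("distances are invariant under affine rescaling of a map", {
  m <- toy_vectors()
  m2 <- m
  m2["a", ] <- 5 * m["a", ] + 3
  expect_equal(unclass(distance_matrix(m)), unclass(distance_matrix(m2)),
               tolerance = 1e-12)
})

test_that("spectral reordering groups planted blocks contiguously", {
  bl <- block_similarity(c(3, 3))
  D <- structure(1 - bl$S, class = c("ale_dist", "matrix"))
  diag(D) <- 0
  # scramble
  set.seed(3)
  perm <- sample(6)
  Ds <- structure(unclass(D)[perm, perm], class = c("ale_dist", "matrix"))
  ord <- reorder_matrix(Ds)
  expect_setequal(ord, 1:6)
  regrouped <- bl$labels[perm][ord]
  # each block occupies a contiguous run
  expect_equal(length(rle(regrouped)$lengths), 2)

  # already block-ordered input keeps blocks contiguous (identity or flip)
  ord0 <- reorder_matrix(D)
  expect_equal(length(rle(bl$labels[ord0])$lengths), 2)
})

test_that("ward dendrogram merges monotonically and handles n = 2", {
  m <- rbind(a = c(1, 2, 3, 5), b = c(2, 4, 7, 8))
  D2 <- distance_matrix(m)
  hc2 <- ward_dendrogram(D2)
  expect_equal(nrow(hc2$merge), 1)

  bl <- block_similarity(c(4, 4), within = 0.85, between = 0.15)
  D <- structure(1 - bl$S, class = c("ale_dist", "matrix")); diag(D) <- 0
  hc <- ward_dendrogram(D)
  expect_true(all(diff(hc$height) >= -1e-12))
  cut <- cut_networks(hc, 2)
  expect_equal(length(unique(cut$cluster)), 2)
})

test_that("planted two-group networks are recovered and the shared reference is central", {
  rsa <- similarity_maps()
  vec <- vectorize_maps(rsa$maps)
  D <- distance_matrix(vec)

  grp <- cut_networks(ward_dendrogram(D[1:8, 1:8]), 2)
  # exact recovery: cluster labels refine the planted grouping
  expect_equal(length(unique(grp$cluster[rsa$group == 1])), 1)
  expect_equal(length(unique(grp$cluster[rsa$group == 2])), 1)
  expect_true(grp$cluster[1] != grp$cluster[5])

  # the reference network shares a center with each group: its mean 1 - r
  # distance to the others is the smallest
  mean_d <- rowSums(D) / (nrow(D) - 1)
  expect_equal(names(which.min(mean_d)), "reference")

  prof <- centrality_profile(D, "reference")
  expect_false("reference" %in% prof$network)
  expect_equal(sum(prof$percent), 100, tolerance = 1e-9)
})

test_that("classical MDS re-embeds Euclidean configurations exactly", {
  set.seed(5)
  pts <- matrix(rnorm(8), 4, 2)
  D <- structure(as.matrix(dist(pts)), class = c("ale_dist", "matrix"))
  rownames(D) <- colnames(D) <- letters[1:4]
  emb <- mds_embed(D, 2)
  expect_lt(emb$stress, 1e-8)
  expect_equal(as.matrix(dist(emb$points)), unclass(D),
               ignore_attr = TRUE, tolerance = 1e-8)

  # equal off-diagonal distances at n = 3 give an equilateral triangle
  D3 <- structure(matrix(1, 3, 3) - diag(3),
                  class = c("ale_dist", "matrix"))
  rownames(D3) <- colnames(D3) <- c("x", "y", "z")
  e3 <- mds_embed(D3, 2)
  side <- as.matrix(dist(e3$points))[upper.tri(diag(3))]
  expect_equal(side, rep(side[1], 3), tolerance = 1e-9)

  # full-dimensional embedding of a Euclidean D has zero stress, and stress
  # never increases with dimension
  pts5 <- matrix(rnorm(15), 5, 3)
  D5 <- structure(as.matrix(dist(pts5)), class = c("ale_dist", "matrix"))
  rownames(D5) <- colnames(D5) <- letters[1:5]
  stresses <- vapply(1:4, function(k) mds_embed(D5, k)$stress, numeric(1))
  expect_lt(stresses[4], 1e-8)
  expect_true(all(diff(stresses) <= 1e-12))
})

test_that("tidiers expose the similarity results as tibbles", {
  m <- toy_vectors()
  D <- distance_matrix(m)
  td <- tidy(D)
  expect_equal(nrow(td), 3)
  expect_named(td, c("network_a", "network_b", "distance"))
  emb <- mds_embed(D, 2)
  expect_named(tidy(emb), c("network", "dim1", "dim2"))
  expect_equal(glance(emb)$n, 3)
})
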