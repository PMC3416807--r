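test_that("kernel closed forms: sigma, half-maximum radius, unit mass", {
  expect_equal(fwhm_to_sigma(10), 10 / (2 * sqrt(2 * log(2))))
  expect_equal(fwhm_to_sigma(10), 4.246609, tolerance = 1e-6)

  # 2.5 mm grid puts points at exactly 5 mm = FWHM/2 from a focus at a
  # voxel center; the kernel there is half the peak (the ratio survives
  # renormalisation)
  g <- toy_mask(40, 2.5)
  focus <- voxel_to_mm(g, mm_to_voxel(g, c(0, 0, 0)))[1, ]
  k <- gaussian_kernel_map(g, focus, fwhm = 10)
  peak_idx <- mm_to_voxel(g, focus)
  at <- function(mm) k$values[matrix(mm_to_voxel(g, mm), 1)]
  expect_equal(at(focus + c(5, 0, 0)) / at(focus), 0.5, tolerance = 1e-9)
  expect_equal(arrayInd(which.max(k$values), dim(k$values)),
               matrix(peak_idx, 1), ignore_attr = TRUE)

  expect_equal(sum(k$values), 1, tolerance = 1e-9)
  g2 <- toy_mask(64, 2)
  k2 <- gaussian_kernel_map(g2, c(3, -7, 11), fwhm = 10)
  expect_equal(sum(k2$values), 1, tolerance = 1e-9)

  expect_error(gaussian_kernel_map(g, focus, fwhm = -1), "fwhm")
})

test_that("ALE reduces to the kernel for one focus and the union closed form for two", {
  g <- toy_mask(32, 2)
  f1 <- tibble::tibble(study_id = "s1", experiment_id = "e1", domain = "",
                       x = 0, y = 0, z = 0)
  a1 <- ale_map(f1, g, ale_params(), quiet = TRUE)
  k <- gaussian_kernel_map(g, c(0, 0, 0), 10)
  expect_equal(a1$values, k$values, tolerance = 1e-12)

  f2 <- dplyr::bind_rows(f1, dplyr::mutate(f1, study_id = "s2",
                                           experiment_id = "e2"))
  a2 <- ale_map(f2, g, ale_params(), quiet = TRUE)
  expect_equal(a2$values, 1 - (1 - k$values)^2, tolerance = 1e-12)
})

test_that("union formula matches the inclusion-exclusion oracle", {
  g <- toy_mask(24, 2)
  set.seed(42)
  foci <- purrr::map_dfr(1:3, function(e)
    tibble::tibble(study_id = sprintf("s%d", e),
                   experiment_id = sprintf("e%d", e), domain = "",
                   x = runif(2, -8, 8), y = runif(2, -8, 8),
                   z = runif(2, -8, 8)))
  a <- ale_map(foci, g, ale_params(), quiet = TRUE)
  vox <- rbind(c(6, 6, 6), c(1, 1, 1), c(12, 9, 4), c(3, 11, 7),
               c(8, 2, 10))
  sets <- lapply(split(foci, foci$experiment_id),
                 function(df) as.matrix(df[, c("x", "y", "z")]))
  expect_equal(a$values[vox], ale_oracle(sets, g, 10, vox),
               tolerance = 1e-12)
})

test_that("ALE is monotone, order-invariant, bounded and grouping-agnostic", {
  g <- toy_mask(24, 2)
  set.seed(7)
  mk <- function(e, n) tibble::tibble(
    study_id = e, experiment_id = e, domain = "",
    x = runif(n, -8, 8), y = runif(n, -8, 8), z = runif(n, -8, 8))
  f12 <- dplyr::bind_rows(mk("e1", 3), mk("e2", 2))
  f123 <- dplyr::bind_rows(f12, mk("e3", 2))
  a12 <- ale_map(f12, g, ale_params(), quiet = TRUE)
  a123 <- ale_map(f123, g, ale_params(), quiet = TRUE)
  expect_true(all(a123$values >= a12$values - 1e-15))
  expect_true(all(a123$values >= 0 & a123$values < 1))
  expect_true(all(a123$values[!g$mask] == 0))

  shuf <- f123[sample(nrow(f123)), ]
  expect_equal(ale_map(shuf, g, ale_params(), quiet = TRUE)$values,
               a123$values, tolerance = 1e-12)

  ungrouped <- ale_map(f123, g, ale_params(by_experiment = FALSE),
                       quiet = TRUE)
  expect_equal(ungrouped$values, a123$values, tolerance = 1e-12)

  expect_error(ale_map(f123[0, ], g, ale_params(), quiet = TRUE), "empty")
})

test_that("empirical p-values follow the add-one convention and nulls are seeded", {
  g <- toy_mask(16, 2)
  fc <- tibble::tibble(study_id = "s", experiment_id = "e", domain = "",
                       x = c(0, 3), y = c(0, -3), z = c(0, 0))
  p <- ale_params(n_permutations = 100, seed = 3)
  nl <- build_null(fc, g, p)
  n <- nl$n_samples
  expect_equal(null_pvalue(nl, max(nl$values) + 1), 1 / (n + 1))
  expect_equal(null_pvalue(nl, 0), 1)
  expect_true(all(diff(nl$values) >= 0) && all(nl$values >= 0))
  # monotone non-increasing p in the ALE value
  v <- seq(0, max(nl$values), length.out = 20)
  expect_true(all(diff(null_pvalue(nl, v)) <= 0))

  nl2 <- build_null(fc, g, p)
  expect_identical(nl$values, nl2$values)
})

test_that("thresholding applies BH and the strict cluster-extent rule", {
  # all-null input yields an empty map
  g <- toy_mask(16, 2)
  fc <- tibble::tibble(study_id = "s", experiment_id = "e", domain = "",
                       x = 0, y = 0, z = 0)
  p <- ale_params(n_permutations = 100, seed = 5)
  nl <- build_null(fc, g, p)
  flat <- volume_map(array(0, dim(g$values)), g$voxel_size, g$origin,
                     g$mask)
  thr <- threshold_map(flat, nl, p)
  expect_equal(sum(thr$values), 0)
  expect_equal(unique(attr(thr, "p_map")$values[g$mask]), 1)

  # BH decisions match the step-up oracle on random p-vectors
  set.seed(11)
  for (i in 1:100) {
    pv <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(p.adjust(pv, "BH") <= 0.05, bh_oracle(pv, 0.05))
  }
  # and reproduce the hand-computed toy decision
  pv <- c(0.01, 0.02, 0.04, 0.9)
  expect_equal(bh_oracle(pv, 0.05), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(p.adjust(pv, "BH") <= 0.05, c(TRUE, TRUE, FALSE, FALSE))
})
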