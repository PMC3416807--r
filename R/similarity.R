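#' Vectorize network maps over the mask
#'
#' Turns each network's (unthresholded) ALE map into a vector of its in-mask
#' voxel values, all maps sharing one fixed voxel scan order (column-major
#' over the grid, recorded in the `"voxel_index"` attribute).
#'
#' @param maps List of `volume_map`s on one grid, named by network.
#' @return A numeric matrix, one row per network, one column per in-mask
#'   voxel; rownames are network names.
#' @export
vectorize_maps <- function(maps) {
  if (length(maps) < 2) abort("need at least 2 maps")
  stop_if_grid_mismatch(maps)
  idx <- which(maps[[1]]$mask)
  m <- t(vapply(maps, function(x) x$values[idx], numeric(length(idx))))
  rownames(m) <- names(maps) %||% sprintf("network_%d", seq_along(maps))
  attr(m, "voxel_index") <- idx
  m
}

#' Rebuild a volume map from a vectorized row
#'
#' Inverse of [vectorize_maps()] for one row.
#' @param values Numeric vector of in-mask values (scan order of
#'   [vectorize_maps()]).
#' @param grid The `volume_map` grid the vector came from.
#' @return A `volume_map`.
#' @export
devectorize_map <- function(values, grid) {
  idx <- which(grid$mask)
  if (length(values) != length(idx))
    abort("value vector does not match the mask size")
  v <- array(0, dim(grid$values))
  v[idx] <- values
  volume_map(v, grid$voxel_size, grid$origin, grid$mask)
}

#' 1 - r distance matrix between network vectors
#'
#' Pairwise Pearson correlation between the vectorized maps; dissimilarity
#' is `1 - r`, so identical patterns are at distance 0 and perfectly
#' anti-correlated ones at 2.
#'
#' @param vectors Matrix from [vectorize_maps()] (rows = networks).
#' @return A symmetric matrix of class `ale_dist` with zero diagonal and
#'   network labels as dimnames.
#' @export
distance_matrix <- function(vectors) {
  if (is.null(rownames(vectors)))
    rownames(vectors) <- sprintf("network_%d", seq_len(nrow(vectors)))
  sds <- apply(vectors, 1, stats::sd)
  if (any(sds == 0))
    abort(sprintf("constant-valued map(s): %s (correlation undefined)",
                  paste(rownames(vectors)[sds == 0], collapse = ", ")))
  D <- 1 - cor(t(vectors))
  diag(D) <- 0
  structure(D, class = c("ale_dist", "matrix"))
}

#' @export
print.ale_dist <- function(x, ...) {
  cat(sprintf("<ale_dist> %d networks; 1 - r distances\n", nrow(x)))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Long-format view of a distance matrix
#' @param x An `ale_dist` matrix.
#' @param ... Unused.
#' @return A tibble with `network_a`, `network_b`, `distance` (upper
#'   triangle).
#' @method tidy ale_dist
#' @export
tidy.ale_dist <- function(x, ...) {
  lab <- rownames(x)
  ut <- which(upper.tri(x), arr.ind = TRUE)
  tibble(network_a = lab[ut[, 1]], network_b = lab[ut[, 2]],
         distance = x[ut])
}

#' Spectral (Fiedler) reordering of a distance matrix
#'
#' Orders the networks so similar ones sit next to each other, concentrating
#' large similarities near the diagonal: networks are sorted by the Fiedler
#' vector (eigenvector of the second-smallest eigenvalue) of the graph
#' Laplacian of the similarity matrix `1 - D`. The global flip ambiguity is
#' resolved by making the first nonzero entry of the Fiedler vector
#' positive.
#'
#' @param D An `ale_dist` matrix.
#' @return An integer permutation of `1:n`, named by network label.
#' @export
reorder_matrix <- function(D) {
  S <- 1 - unclass(D)
  diag(S) <- 0
  L <- diag(rowSums(S)) - S
  e <- eigen(L, symmetric = TRUE)
  f <- e$vectors[, ncol(S) - 1L]
  nz <- which(abs(f) > 1e-12)[1]
  if (length(nz) && f[nz] < 0) f <- -f
  p <- order(f)
  names(p) <- rownames(D)[p]
  p
}

#' Ward dendrogram of the task networks
#'
#' Agglomerative hierarchical clustering of the `1 - r` distances under
#' Ward's minimum-variance criterion. `"ward.D2"` (default) applies Ward's
#' variance update to the distances themselves (squaring internally);
#' `"ward.D"` treats the supplied dissimilarities as already squared.
#'
#' @param D An `ale_dist` matrix.
#' @param method `"ward.D2"` or `"ward.D"`.
#' @return An object of class `ale_ward` (also `hclust`).
#' @export
ward_dendrogram <- function(D, method = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  hc <- hclust(stats::as.dist(unclass(D)), method = method)
  class(hc) <- c("ale_ward", "hclust")
  hc
}

#' Cut a network dendrogram into k clusters
#'
#' @param tree An `ale_ward` dendrogram.
#' @param k Number of clusters (default 2).
#' @return A tibble with `network` and `cluster` (integer labels).
#' @export
cut_networks <- function(tree, k = 2) {
  cl <- cutree(tree, k = k)
  tibble(network = names(cl), cluster = unname(cl))
}

#' @method tidy ale_ward
#' @export
tidy.ale_ward <- function(x, ...) {
  tibble(merge1 = x$merge[, 1], merge2 = x$merge[, 2], height = x$height)
}

#' @method glance ale_ward
#' @export
glance.ale_ward <- function(x, ...) {
  tibble(n = length(x$labels %||% x$order), method = x$method,
         max_height = max(x$height))
}

#' Classical multidimensional scaling of network distances
#'
#' Torgerson's classical MDS: double-centering of the squared
#' dissimilarities and top-d spectral decomposition, giving coordinates
#' whose pairwise Euclidean distances approximate `D`. The reported stress
#' is Kruskal's stress-1,
#' `sqrt(sum((D - Dhat)^2) / sum(D^2))` over the off-diagonal entries.
#'
#' @param D An `ale_dist` matrix.
#' @param d Embedding dimension (default 2).
#' @return An object of class `ale_mds`: `points` (n x d matrix), `stress`,
#'   `eig`, `d`.
#' @export
mds_embed <- function(D, d = 2) {
  n <- nrow(D)
  if (d < 1 || d > n - 1) abort("`d` must be in 1..(n-1)")
  fit <- cmdscale(unclass(D), k = d, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < d)
    pts <- cbind(pts, matrix(0, n, d - ncol(pts)))
  rownames(pts) <- rownames(D)
  Dhat <- as.matrix(dist(pts))
  off <- upper.tri(D)
  stress <- sqrt(sum((unclass(D)[off] - Dhat[off])^2) /
                   sum(unclass(D)[off]^2))
  structure(list(points = pts, stress = stress, eig = fit$eig, d = d),
            class = "ale_mds")
}

#' @export
print.ale_mds <- function(x, ...) {
  cat(sprintf("<ale_mds> %d networks in %d dimensions; stress-1 = %.4g\n",
              nrow(x$points), x$d, x$stress))
  invisible(x)
}

#' @method tidy ale_mds
#' @export
tidy.ale_mds <- function(x, ...) {
  out <- as_tibble(x$points, .name_repair = ~ sprintf("dim%d",
                                                      seq_along(.x)))
  dplyr::bind_cols(tibble(network = rownames(x$points)), out)
}

#' @method glance ale_mds
#' @export
glance.ale_mds <- function(x, ...) {
  tibble(n = nrow(x$points), d = x$d, stress = x$stress)
}

#' Similarity profile of the networks against a reference
#'
#' Ranks the other networks by their spatial similarity `1 - D` to a
#' reference network (e.g. the pain network), with the similarity shares
#' normalized to percentages summing to 100 over the non-reference networks.
#'
#' @param D An `ale_dist` matrix.
#' @param reference Label of the reference network.
#' @return A tibble with `network`, `similarity`, `percent`, sorted by
#'   decreasing similarity.
#' @export
centrality_profile <- function(D, reference) {
  lab <- rownames(D)
  if (!reference %in% lab) abort(sprintf("unknown network: %s", reference))
  sim <- 1 - D[reference, setdiff(lab, reference)]
  tibble(network = names(sim), similarity = unname(sim),
         percent = 100 * unname(sim) / sum(sim)) %>%
    arrange(dplyr::desc(.data$similarity))
}
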