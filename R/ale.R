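#' ALE analysis parameters
#'
#' Bundles the tunable parameters of the activation-likelihood estimation
#' chain. Defaults follow standard coordinate-based meta-analysis practice:
#' a fixed 10 mm FWHM Gaussian kernel for every experiment, voxelwise
#' false-discovery-rate control at q = 0.05 and a strict minimum cluster
#' extent of 100 mm^3 (clusters of volume <= 100 mm^3 are removed).
#'
#' @param fwhm Kernel full width at half maximum in mm (> 0).
#' @param n_permutations Number of focus-randomisation permutations used to
#'   build the null distribution (>= 100).
#' @param q_fdr Benjamini-Hochberg false discovery rate level, in (0, 1).
#' @param min_cluster_mm3 Minimum cluster volume in mm^3; surviving clusters
#'   must exceed this volume.
#' @param connectivity Voxel connectivity for cluster labelling, 26 or 6.
#' @param by_experiment Group foci into per-experiment modeled-activation
#'   maps before the probabilistic union (`TRUE`, default) or take the union
#'   over all foci directly. With union-combined modeled-activation maps the
#'   two are algebraically identical; the switch exists to make that
#'   property checkable.
#' @param seed Integer seed for the permutation RNG (`NULL` = leave the
#'   global RNG alone).
#' @return A list of class `ale_params`.
#' @export
ale_params <- function(fwhm = 10, n_permutations = 1000, q_fdr = 0.05,
                       min_cluster_mm3 = 100, connectivity = 26,
                       by_experiment = TRUE, seed = NULL) {
  if (!is.numeric(fwhm) || fwhm <= 0) abort("`fwhm` must be > 0")
  if (n_permutations < 100) abort("`n_permutations` must be >= 100")
  if (q_fdr <= 0 || q_fdr >= 1) abort("`q_fdr` must be in (0, 1)")
  if (min_cluster_mm3 < 0) abort("`min_cluster_mm3` must be >= 0")
  if (!connectivity %in% c(6, 26)) abort("`connectivity` must be 6 or 26")
  structure(list(fwhm = fwhm, n_permutations = as.integer(n_permutations),
                 q_fdr = q_fdr, min_cluster_mm3 = min_cluster_mm3,
                 connectivity = connectivity,
                 by_experiment = isTRUE(by_experiment), seed = seed),
            class = "ale_params")
}

#' Convert kernel FWHM to Gaussian standard deviation
#'
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))`; for the conventional 10 mm FWHM
#' this gives sigma = 4.2466 mm.
#'
#' @param fwhm Full width at half maximum, mm.
#' @return Standard deviation in mm.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Separable evaluation of an isotropic 3-D Gaussian (density x voxel volume)
# centred on `focus` over the whole grid; masked; optionally renormalised to
# unit mass over the in-mask voxels.
kernel_values <- function(grid, focus, sigma, normalize = TRUE) {
  d <- dim(grid$values)
  g <- lapply(1:3, function(a) {
    co <- grid$origin[a] + (seq_len(d[a]) - 1) * grid$voxel_size[a]
    exp(-(co - focus[a])^2 / (2 * sigma^2))
  })
  k <- outer(outer(g[[1]], g[[2]]), g[[3]])
  k <- k * ((2 * pi * sigma^2)^(-1.5) * voxel_volume(grid))
  k[!grid$mask] <- 0
  if (normalize) {
    s <- sum(k)
    if (s <= 0) abort("kernel has zero mass inside the mask")
    k <- k / s
  }
  k
}

#' Gaussian kernel map for a single focus
#'
#' Models the spatial uncertainty of one reported activation peak as an
#' isotropic 3-D Gaussian with the given FWHM, evaluated at voxel centres,
#' scaled by the voxel volume and renormalised to sum to 1 over the in-mask
#' grid — a per-voxel activation probability.
#'
#' @param grid A `volume_map` supplying grid and mask.
#' @param focus Length-3 mm coordinate; must be in-mask.
#' @param fwhm Kernel FWHM in mm.
#' @param normalize Renormalise to unit mass over the mask (default `TRUE`;
#'   `FALSE` returns raw density times voxel volume).
#' @return A `volume_map` of kernel probabilities.
#' @export
gaussian_kernel_map <- function(grid, focus, fwhm = 10, normalize = TRUE) {
  if (fwhm <= 0) abort("`fwhm` must be > 0")
  if (!in_mask(grid, focus)) abort("focus lies outside the mask")
  k <- kernel_values(grid, focus, fwhm_to_sigma(fwhm), normalize)
  volume_map(k, grid$voxel_size, grid$origin, grid$mask)
}

# foci tibble -> list of per-experiment mm coordinate matrices, out-of-mask
# foci excluded (with QC message), experiments left with no in-mask foci
# dropped with a warning.
foci_by_experiment <- function(foci, grid, quiet = FALSE) {
  foci <- flag_foci(foci, grid, quiet = quiet)
  kept <- foci %>% filter(.data$in_mask)
  if (!nrow(kept)) abort("no in-mask foci: nothing to model")
  dropped <- setdiff(unique(foci$experiment_id), unique(kept$experiment_id))
  if (length(dropped))
    warn(sprintf("experiments with no in-mask foci dropped: %s",
                 paste(dropped, collapse = ", ")))
  split_ids <- factor(kept$experiment_id, levels = unique(kept$experiment_id))
  lapply(split(kept[, c("x", "y", "z")], split_ids),
         function(df) as.matrix(df))
}

ale_from_coords <- function(coord_sets, grid, sigma) {
  acc <- array(1, dim(grid$values))
  for (xyz in coord_sets) {
    for (r in seq_len(nrow(xyz))) {
      acc <- acc * (1 - kernel_values(grid, xyz[r, ], sigma))
    }
  }
  a <- 1 - acc
  a[!grid$mask] <- 0
  a
}

#' Activation likelihood estimation map
#'
#' Computes the ALE statistic at every in-mask voxel. Each focus is blurred
#' with a normalised Gaussian kernel; each experiment's foci combine into a
#' modeled-activation map `MA_i(v) = 1 - prod_f (1 - k_f(v))`; experiments
#' combine as the probabilistic union `ALE(v) = 1 - prod_i (1 - MA_i(v))`.
#' With union-combined modeled-activation maps the grouped and ungrouped
#' computations coincide, so `by_experiment` does not change the result.
#'
#' @param foci Foci tibble (see [read_foci_table()]); grouped by
#'   `experiment_id`. Out-of-mask foci are excluded from kernels (flagged,
#'   not silently dropped — a message reports the count).
#' @param grid A `volume_map` supplying grid and mask.
#' @param params An [ale_params()] object.
#' @param quiet Suppress the out-of-mask QC message.
#' @return A `volume_map` of ALE values in `[0, 1)`.
#' @export
ale_map <- function(foci, grid, params = ale_params(), quiet = FALSE) {
  sets <- foci_by_experiment(foci, grid, quiet = quiet)
  if (!params$by_experiment) sets <- list(do.call(rbind, sets))
  vals <- ale_from_coords(sets, grid, fwhm_to_sigma(params$fwhm))
  volume_map(vals, grid$voxel_size, grid$origin, grid$mask)
}

#' Permutation null distribution of ALE values
#'
#' Relocates every focus independently and uniformly over the in-mask voxel
#' centres (preserving per-experiment focus counts), recomputes the ALE map,
#' and pools all in-mask voxel values across `n_permutations` permutations
#' into one empirical null sample. Deterministic given `params$seed`.
#'
#' @inheritParams ale_map
#' @return An object of class `ale_null`: sorted pooled null values,
#'   `n_samples`, and the generating parameters.
#' @export
build_null <- function(foci, grid, params = ale_params(), quiet = TRUE) {
  sets <- foci_by_experiment(foci, grid, quiet = quiet)
  counts <- vapply(sets, nrow, integer(1))
  sigma <- fwhm_to_sigma(params$fwhm)
  in_idx <- which(grid$mask)
  centers <- voxel_to_mm(grid, arrayInd(in_idx, dim(grid$values)))
  vals <- with_rng(params$seed, {
    unlist(lapply(seq_len(params$n_permutations), function(p) {
      draw <- sample.int(nrow(centers), sum(counts), replace = TRUE)
      xyz <- centers[draw, , drop = FALSE]
      sets_p <- split.data.frame(xyz, rep(seq_along(counts), counts))
      a <- ale_from_coords(sets_p, grid, sigma)
      a[in_idx]
    }), use.names = FALSE)
  })
  structure(list(values = sort(vals), n_samples = length(vals),
                 n_permutations = params$n_permutations, params = params),
            class = "ale_null")
}

#' @export
print.ale_null <- function(x, ...) {
  cat(sprintf("<ale_null> %d pooled values from %d permutations; max %g\n",
              x$n_samples, x$n_permutations, max(x$values)))
  invisible(x)
}

#' Empirical p-values against an ALE null
#'
#' `p = (1 + #\{null >= v\}) / (1 + n_samples)` — the add-one convention, so
#' p is never exactly 0 and a value exceeding every null sample gets
#' `1 / (n_samples + 1)`.
#'
#' @param null An `ale_null`.
#' @param values Numeric vector of observed ALE values.
#' @return Numeric vector of p-values in (0, 1].
#' @export
null_pvalue <- function(null, values) {
  n <- null$n_samples
  n_ge <- n - findInterval(values, null$values, left.open = TRUE)
  (1 + n_ge) / (1 + n)
}

#' Voxelwise p-value map
#'
#' @param ale An ALE `volume_map`.
#' @param null An `ale_null` built on the same grid.
#' @return A `volume_map` of empirical p-values (0 outside the mask).
#' @export
p_value_map <- function(ale, null) {
  p <- array(0, dim(ale$values))
  p[ale$mask] <- null_pvalue(null, ale$values[ale$mask])
  volume_map(p, ale$voxel_size, ale$origin, ale$mask)
}

#' Threshold an ALE map
#'
#' Voxelwise empirical p-values against the permutation null, Benjamini-
#' Hochberg FDR control at `q_fdr`, then cluster-extent filtering: surviving
#' voxels are grouped into connected components and components of volume
#' `<= min_cluster_mm3` are removed (strict `k > min_cluster_mm3`).
#'
#' @param ale An ALE `volume_map`.
#' @param null An `ale_null` built from the same grid.
#' @param params An [ale_params()] object.
#' @return A binary `volume_map`; the voxelwise p-value map is attached as
#'   attribute `"p_map"`.
#' @export
threshold_map <- function(ale, null, params = ale_params()) {
  p_map <- p_value_map(ale, null)
  p <- p_map$values[ale$mask]
  sig <- p.adjust(p, method = "BH") <= params$q_fdr
  b <- array(0, dim(ale$values))
  b[ale$mask] <- as.numeric(sig)
  bmap <- volume_map(b, ale$voxel_size, ale$origin, ale$mask)
  bmap <- filter_clusters(bmap, params$min_cluster_mm3, params$connectivity)
  attr(bmap, "p_map") <- p_map
  bmap
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# state; seed = NULL runs the code with the ambient RNG.
with_rng <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
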