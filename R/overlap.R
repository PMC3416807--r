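#' Probabilistic overlap map of thresholded network maps
#'
#' At each voxel, the fraction of networks whose (already thresholded,
#' binary) map is active there: summing the per-network voxel values and
#' dividing by the number of networks. The conjunction of the networks is
#' the voxels where this fraction is exactly 1. `binary = FALSE` averages
#' the raw map values instead of binary membership, for continuous inputs.
#'
#' @param maps List of binary `volume_map`s on one shared grid, optionally
#'   named by network.
#' @param binary Treat inputs as binary membership (`values != 0`), the
#'   default; `FALSE` averages raw values.
#' @return A `volume_map` of class `overlap_map` with values in
#'   `\{0, 1/N, ..., 1\}`; the integer count map is kept as attribute
#'   `"counts"`, network names as `"network_names"`, N as `"n_networks"`.
#' @export
probability_overlap <- function(maps, binary = TRUE) {
  if (length(maps) < 2) abort("need at least 2 maps")
  stop_if_grid_mismatch(maps)
  g <- maps[[1]]
  acc <- array(0, dim(g$values))
  for (m in maps) acc <- acc + if (binary) (m$values != 0) else m$values
  n <- length(maps)
  out <- volume_map(acc / n, g$voxel_size, g$origin, g$mask)
  attr(out, "counts") <- acc
  attr(out, "n_networks") <- n
  attr(out, "network_names") <-
    names(maps) %||% sprintf("network_%d", seq_len(n))
  class(out) <- c("overlap_map", class(out))
  out
}

#' Conjunction (100% overlap) of the networks
#'
#' Voxels represented in every network: the overlap count equals N exactly
#' (an integer comparison, no floating-point tolerance) — equivalently the
#' voxelwise logical AND of the N binary maps.
#'
#' @param overlap An `overlap_map` from [probability_overlap()].
#' @return A binary `volume_map`.
#' @export
conjunction <- function(overlap) {
  if (!inherits(overlap, "overlap_map"))
    abort("`overlap` must come from probability_overlap()")
  counts <- attr(overlap, "counts")
  n <- attr(overlap, "n_networks")
  volume_map(array(as.numeric(counts == n), dim(counts)),
             overlap$voxel_size, overlap$origin, overlap$mask)
}

#' Lowest-overlap fraction of the involved voxels
#'
#' Among voxels touched by at least one network, selects roughly the
#' `fraction` with the lowest overlap values. Selection is stratum-wise over
#' the discrete overlap values so ties are never split arbitrarily: whole
#' value-strata are admitted from the lowest value upward while the
#' cumulative voxel count stays within the quota
#' `ceiling(fraction * n_nonzero)`; a stratum that would overshoot the quota
#' is excluded entirely. If even the lowest stratum overshoots the result is
#' empty — except in the degenerate case of a single uniform stratum, where
#' all voxels are returned with a warning.
#'
#' @param overlap An `overlap_map`.
#' @param fraction Proportion of nonzero voxels to select, in (0, 1);
#'   default 0.20.
#' @return A binary `volume_map`.
#' @export
low_overlap_region <- function(overlap, fraction = 0.20) {
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1)")
  v <- overlap$values
  nz <- which(v > 0)
  out <- array(0, dim(v))
  if (!length(nz)) {
    warn("overlap map has no nonzero voxels; returning an empty map")
    return(volume_map(out, overlap$voxel_size, overlap$origin, overlap$mask))
  }
  quota <- ceiling(fraction * length(nz))
  strata <- sort(unique(v[nz]))
  counts <- vapply(strata, function(s) sum(v[nz] == s), numeric(1))
  admit <- cumsum(counts) <= quota
  if (!any(admit)) {
    if (length(strata) == 1L) {
      warn("uniform overlap map: lowest stratum is everything; returning all nonzero voxels")
      admit <- TRUE
    } else {
      warn("lowest overlap stratum exceeds the quota; returning an empty map")
    }
  }
  keep <- strata[admit]
  if (length(keep)) out[nz[v[nz] %in% keep]] <- 1
  volume_map(out, overlap$voxel_size, overlap$origin, overlap$mask)
}
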