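#' Select experiments co-activating seed regions
#'
#' Meta-analytic connectivity modeling starts from the experiments that
#' report at least one focus inside a seed region. A focus counts as inside
#' a region when its nearest voxel is active there (no dilation by default;
#' `dilate_mm` pads each region by a given radius for studies that prefer
#' padded seeds). With several regions the default keeps experiments hitting
#' *any* region; `require_all = TRUE` demands a focus in *every* region.
#'
#' @param foci Foci tibble.
#' @param rois List of binary `volume_map`s (or a single map) on the
#'   analysis grid.
#' @param require_all Require a hit in every region (default `FALSE`: any).
#' @param dilate_mm Dilate each region by this radius (mm) before testing.
#' @return The selected rows of `foci` (order preserved); attribute
#'   `"selection"` holds a per-experiment report tibble with one logical
#'   column per region.
#' @export
select_coactivating <- function(foci, rois, require_all = FALSE,
                                dilate_mm = 0) {
  if (is_volume_map(rois)) rois <- list(rois)
  if (!length(rois)) abort("need at least one ROI")
  stop_if_grid_mismatch(rois)
  foci <- check_foci(foci)
  if (dilate_mm > 0) rois <- lapply(rois, dilate_map, mm = dilate_mm)
  roi_names <- names(rois) %||% sprintf("roi_%d", seq_along(rois))
  xyz <- as.matrix(foci[, c("x", "y", "z")])
  hit <- vapply(rois, function(r) {
    idx <- mm_to_voxel(r, xyz)
    d <- dim(r$values)
    ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
      idx[, 2] >= 1 & idx[, 2] <= d[2] &
      idx[, 3] >= 1 & idx[, 3] <= d[3]
    h <- logical(nrow(idx))
    h[ok] <- r$values[idx[ok, , drop = FALSE]] != 0
    h
  }, logical(nrow(foci)))
  hit <- matrix(hit, nrow = nrow(foci),
                dimnames = list(NULL, roi_names))
  report <- as_tibble(cbind(
    tibble(experiment_id = foci$experiment_id), as.data.frame(hit))) %>%
    group_by(.data$experiment_id) %>%
    summarise(across(all_of(roi_names), any), .groups = "drop")
  sel_flag <- if (require_all) apply(report[roi_names], 1, all)
  else apply(report[roi_names], 1, any)
  report$selected <- sel_flag
  keep_ids <- report$experiment_id[sel_flag]
  out <- foci %>% filter(.data$experiment_id %in% keep_ids)
  attr(out, "selection") <- report
  out
}

# binary dilation by a spherical structuring element of radius `mm`
dilate_map <- function(map, mm) {
  r_vox <- ceiling(mm / map$voxel_size)
  offs <- as.matrix(expand.grid(-r_vox[1]:r_vox[1], -r_vox[2]:r_vox[2],
                                -r_vox[3]:r_vox[3]))
  d_mm2 <- colSums(t(offs^2) * map$voxel_size^2)
  offs <- offs[d_mm2 <= mm^2, , drop = FALSE]
  dims <- dim(map$values)
  act <- arrayInd(which(map$values != 0), dims)
  out <- array(0, dims)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(act, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    out[nb[ok, , drop = FALSE]] <- 1
  }
  volume_map(out, map$voxel_size, map$origin, map$mask)
}

#' Meta-analytic connectivity map
#'
#' Runs the full ALE chain (map, permutation null, FDR + cluster-extent
#' thresholding) on the experiments selected by [select_coactivating()],
#' giving the co-activation network of the seed regions.
#'
#' @inheritParams select_coactivating
#' @param grid Analysis grid (`volume_map`).
#' @param params An [ale_params()] object.
#' @return A list of class `macm_result`: `ale` (the ALE map of the selected
#'   subset), `thresholded` (binary map), `null`, `selection` (report
#'   tibble), `n_selected`, `params`.
#' @export
macm_map <- function(foci, rois, grid, params = ale_params(),
                     require_all = FALSE, dilate_mm = 0) {
  sel <- select_coactivating(foci, rois, require_all = require_all,
                             dilate_mm = dilate_mm)
  if (!nrow(sel)) abort("empty selection: no experiment co-activates the seed region(s)")
  ale <- ale_map(sel, grid, params, quiet = TRUE)
  null <- build_null(sel, grid, params)
  thr <- threshold_map(ale, null, params)
  structure(list(ale = ale, thresholded = thr, null = null,
                 selection = attr(sel, "selection"),
                 n_selected = length(unique(sel$experiment_id)),
                 params = params),
            class = "macm_result")
}

#' @export
print.macm_result <- function(x, ...) {
  cat(sprintf("<macm_result> %d experiments selected; %d suprathreshold voxels\n",
              x$n_selected, sum(x$thresholded$values != 0)))
  invisible(x)
}

#' @describeIn macm_map One-line summary: selection counts and
#'   suprathreshold volume.
#' @param x A `macm_result`.
#' @param ... Unused.
#' @export
glance.macm_result <- function(x, ...) {
  tibble(n_selected = x$n_selected,
         n_experiments = nrow(x$selection),
         n_suprathreshold = sum(x$thresholded$values != 0),
         volume_mm3 = sum(x$thresholded$values != 0) *
           voxel_volume(x$thresholded))
}
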