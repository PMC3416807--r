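#' Write a volume map to a NIfTI-1 file
#'
#' Emits a NIfTI-1 volume with a diagonal affine encoding the voxel size and
#' origin (sform code 2). The mask is not stored in the NIfTI itself —
#' out-of-mask voxels are written as 0; pass `mask_path` to additionally
#' write the mask as a companion 0/1 volume.
#'
#' @param map A `volume_map`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param mask_path Optional path for a companion mask volume.
#' @return `path`, invisibly.
#' @export
write_volume <- function(map, path, mask_path = NULL) {
  if (!is_volume_map(map)) abort("`map` must be a volume_map")
  aff <- cbind(diag(map$voxel_size), map$origin)
  h <- RNifti::niftiHeader(list(
    pixdim = c(1, map$voxel_size, 0, 0, 0, 0),
    srow_x = aff[1, ], srow_y = aff[2, ], srow_z = aff[3, ],
    sform_code = 2L, qform_code = 0L))
  img <- RNifti::asNifti(map$values, reference = h, datatype = "double")
  RNifti::writeNifti(img, path)
  if (!is.null(mask_path)) {
    mimg <- RNifti::asNifti(array(as.numeric(map$mask), dim(map$mask)),
                            reference = h, datatype = "double")
    RNifti::writeNifti(mimg, mask_path)
  }
  invisible(path)
}

#' Read a volume map from a NIfTI-1 file
#'
#' Only axis-aligned volumes (diagonal affine, positive voxel sizes) are
#' supported; anything else errors rather than being silently resampled.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param mask Optional mask: a logical array, a `volume_map`, or a path to a
#'   0/1 NIfTI volume on the same grid. Default: all voxels in-mask.
#' @return A `volume_map`.
#' @export
read_volume <- function(path, mask = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  x <- unclass(RNifti::xform(img))
  rot <- x[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-6)
    abort(sprintf("unsupported NIfTI dialect in %s: affine is not diagonal",
                  path))
  vs <- diag(rot)
  if (any(vs <= 0))
    abort(sprintf("unsupported NIfTI dialect in %s: non-positive voxel sizes",
                  path))
  vals <- array(as.numeric(img), dim(img)[1:3])
  if (is.character(mask)) mask <- read_volume(mask)$values != 0
  if (is_volume_map(mask)) mask <- mask$mask
  volume_map(vals, vs, x[1:3, 4], mask)
}
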