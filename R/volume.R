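#' Scalar volume on a regular voxel grid
#'
#' A `volume_map` holds a scalar field sampled on an axis-aligned 3-D voxel
#' grid together with the affine metadata needed to move between millimetre
#' (stereotactic, MNI-style) coordinates and voxel indices, and a logical
#' brain mask. All public interfaces in the package speak millimetres; voxel
#' indices are an internal detail. Coordinates refer to voxel *centres*:
#' voxel `(i, j, k)` (1-based, R convention) sits at
#' `origin + (c(i, j, k) - 1) * voxel_size`.
#'
#' Values outside the mask are forced to exactly 0 on construction, an
#' invariant every operation in the package preserves.
#'
#' @param values Numeric 3-D array of voxel values.
#' @param voxel_size Numeric length-3 (or scalar) voxel edge length in mm.
#' @param origin Numeric length-3: mm coordinate of the centre of the first
#'   voxel (`values[1, 1, 1]`).
#' @param mask Logical array of the same dimension as `values`, or `NULL` for
#'   an all-`TRUE` mask.
#' @return An object of class `volume_map`.
#' @export
volume_map <- function(values, voxel_size, origin, mask = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    abort("`values` must be a 3-D array.")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    abort("`voxel_size` must be 3 positive finite numbers (mm).")
  if (length(origin) != 3L || any(!is.finite(origin)))
    abort("`origin` must be 3 finite numbers (mm).")
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  if (!identical(dim(mask), dim(values)))
    abort("`mask` must have the same dimensions as `values`.")
  storage.mode(values) <- "double"
  mask <- array(as.logical(mask), dim(values))
  if (anyNA(mask)) abort("`mask` must not contain NA.")
  values[!mask] <- 0
  structure(
    list(values = values, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin), mask = mask),
    class = "volume_map"
  )
}

#' @export
print.volume_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<volume_map> %d x %d x %d voxels, %g x %g x %g mm, origin (%g, %g, %g)\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  in-mask voxels: %d; value range [%g, %g]\n",
              sum(x$mask), min(x$values[x$mask]), max(x$values[x$mask])))
  invisible(x)
}

#' @export
dim.volume_map <- function(x) dim(x$values)

is_volume_map <- function(x) inherits(x, "volume_map")

#' Volume of one voxel in cubic millimetres
#' @param map A `volume_map`.
#' @return Scalar voxel volume in mm^3.
#' @export
voxel_volume <- function(map) prod(map$voxel_size)

#' Check that two volumes share a grid
#'
#' Same dimensions, voxel size, origin and mask.
#' @param a,b `volume_map` objects.
#' @return `TRUE` or `FALSE`.
#' @export
same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-9)) &&
    identical(a$mask, b$mask)
}

stop_if_grid_mismatch <- function(maps) {
  ok <- vapply(maps[-1], same_grid, logical(1), b = maps[[1]])
  if (!all(ok))
    abort(sprintf("maps %s are not on the grid of map 1",
                  paste(which(!ok) + 1L, collapse = ", ")))
  invisible(TRUE)
}

#' Convert millimetre coordinates to (nearest) voxel indices
#'
#' @param map A `volume_map` supplying the grid.
#' @param mm Numeric matrix (n x 3) or length-3 vector of mm coordinates.
#' @param nearest Round to the nearest voxel (default) or return fractional
#'   indices.
#' @return An n x 3 matrix of 1-based voxel indices.
#' @export
mm_to_voxel <- function(map, mm, nearest = TRUE) {
  mm <- rbind_coords(mm)
  idx <- sweep(sweep(mm, 2, map$origin, "-"), 2, map$voxel_size, "/") + 1
  if (nearest) idx <- round(idx)
  idx
}

#' Convert voxel indices to millimetre coordinates of voxel centres
#'
#' @param map A `volume_map` supplying the grid.
#' @param voxel Numeric matrix (n x 3) or length-3 vector of 1-based indices.
#' @return An n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(map, voxel) {
  voxel <- rbind_coords(voxel)
  sweep(sweep(voxel - 1, 2, map$voxel_size, "*"), 2, map$origin, "+")
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 3L)
  if (ncol(x) != 3L) abort("coordinates must have 3 columns (x, y, z)")
  storage.mode(x) <- "double"
  x
}

#' Are mm points inside the grid and mask?
#'
#' A point is in-mask when its nearest voxel lies inside the grid and that
#' voxel's mask entry is `TRUE`.
#' @param map A `volume_map`.
#' @param mm n x 3 matrix or length-3 vector of mm coordinates.
#' @return Logical vector of length n.
#' @export
in_mask <- function(map, mm) {
  idx <- mm_to_voxel(map, mm)
  d <- dim(map$values)
  inside <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
    idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- logical(nrow(idx))
  if (any(inside))
    out[inside] <- map$mask[idx[inside, , drop = FALSE]]
  out
}

#' Toy analysis grid
#'
#' A cubic mask of side `extent_mm` centred on `center`, at isotropic
#' `voxel_size` resolution — the desk-scale stand-in for a brain mask used by
#' the synthetic scenarios. 2 mm isotropic voxels are the default analysis
#' resolution, which keeps the 100 mm^3 cluster-extent rule meaningful
#' (100 mm^3 = 12.5 voxels).
#'
#' @param extent_mm Side length of the cube in mm (default 64).
#' @param voxel_size Isotropic voxel edge in mm (default 2).
#' @param center mm coordinate of the cube centre (default the origin).
#' @return A `volume_map` of zeros with an all-`TRUE` mask.
#' @export
toy_mask <- function(extent_mm = 64, voxel_size = 2, center = c(0, 0, 0)) {
  n <- as.integer(round(extent_mm / voxel_size))
  if (n < 2) abort("grid must have at least 2 voxels per axis")
  origin <- center - (n - 1) * voxel_size / 2
  volume_map(array(0, c(n, n, n)), voxel_size, origin)
}

#' Spherical binary region on a grid
#'
#' Marks the voxels whose centres lie within `radius_mm` of `center`;
#' used to define seed regions and planted ground-truth spheres.
#'
#' @param grid A `volume_map` supplying the grid.
#' @param center Length-3 mm coordinate.
#' @param radius_mm Sphere radius in mm.
#' @return A binary `volume_map` (1 inside the sphere and mask, 0 elsewhere).
#' @export
sphere_map <- function(grid, center, radius_mm) {
  d <- dim(grid$values)
  ax <- lapply(1:3, function(a)
    grid$origin[a] + (seq_len(d[a]) - 1) * grid$voxel_size[a] - center[a])
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  volume_map(array(as.numeric(d2 <= radius_mm^2), d),
             grid$voxel_size, grid$origin, grid$mask)
}

#' Label connected components of a binary map
#'
#' Components are defined on the voxel adjacency graph (26-neighbourhood by
#' default, 6-neighbourhood optional) restricted to nonzero voxels; labels
#' are arbitrary positive integers, 0 marks background.
#'
#' @param map A binary `volume_map`.
#' @param connectivity 26 (faces, edges and corners) or 6 (faces only).
#' @return An integer 3-D array of component labels.
#' @export
label_components <- function(map, connectivity = 26) {
  if (!connectivity %in% c(6, 26)) abort("`connectivity` must be 6 or 26")
  dims <- dim(map$values)
  idx <- which(map$values != 0)
  lab <- array(0L, dims)
  if (!length(idx)) return(lab)
  coord <- arrayInd(idx, dims)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1L, , drop = FALSE]
  # one direction per neighbour pair is enough for an undirected graph
  offs <- offs[offs %*% c(9, 3, 1) > 0, , drop = FALSE]
  pos <- integer(prod(dims)); pos[idx] <- seq_along(idx)
  edges <- lapply(seq_len(nrow(offs)), function(r) {
    nb <- sweep(coord, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lin <- nb[ok, 1] + (nb[ok, 2] - 1) * dims[1] +
      (nb[ok, 3] - 1) * dims[1] * dims[2]
    j <- pos[lin]
    cbind(which(ok)[j > 0], j[j > 0])
  })
  e <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(e)) g <- igraph::add_edges(g, t(e))
  lab[idx] <- igraph::components(g)$membership
  lab
}

#' Remove small connected components
#'
#' Drops components whose volume (voxel count times voxel volume) does not
#' exceed `min_mm3` — the strict `k > min_mm3` cluster-extent rule.
#'
#' @param map A binary `volume_map`.
#' @param min_mm3 Minimum component volume in mm^3; components with volume
#'   `<= min_mm3` are removed.
#' @param connectivity Passed to [label_components()].
#' @return A binary `volume_map`.
#' @export
filter_clusters <- function(map, min_mm3 = 100, connectivity = 26) {
  lab <- label_components(map, connectivity)
  if (!any(lab > 0)) return(map)
  sizes <- tabulate(lab) * voxel_volume(map)
  keep <- which(sizes > min_mm3)
  volume_map(array(as.numeric(lab %in% keep), dim(map$values)),
             map$voxel_size, map$origin, map$mask)
}

#' Dice coefficient between two binary maps
#'
#' `2 |A n B| / (|A| + |B|)`; spatial agreement between two binary maps.
#' Defined as 0 when both maps are empty.
#'
#' @param a,b Binary `volume_map`s on the same grid.
#' @return A list with `dice`, `n_a`, `n_b`, `n_intersect`.
#' @export
dice_coefficient <- function(a, b) {
  stop_if_grid_mismatch(list(a, b))
  av <- a$values != 0; bv <- b$values != 0
  na <- sum(av); nb <- sum(bv); ni <- sum(av & bv)
  dice <- if (na + nb == 0) 0 else 2 * ni / (na + nb)
  list(dice = dice, n_a = na, n_b = nb, n_intersect = ni)
}

#' Tabulate a volume map
#'
#' Long-format view of the in-mask voxels: mm coordinates and value.
#' @param x A `volume_map`.
#' @param ... Unused.
#' @return A tibble with columns `x`, `y`, `z`, `value`.
#' @method tidy volume_map
#' @export
tidy.volume_map <- function(x, ...) {
  idx <- which(x$mask)
  co <- voxel_to_mm(x, arrayInd(idx, dim(x$values)))
  vals <- x$values[idx]  # grab before tibble()'s `x` column masks the map
  tibble(x = co[, 1], y = co[, 2], z = co[, 3], value = vals)
}
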