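#' Construct a voxel grid
#'
#' A voxel grid couples an array shape with a 4x4 affine that maps 0-based
#' voxel indices to world coordinates in millimetres (RAS convention). All
#' spatial quantities downstream (voxel volume, subvolume thresholds in cm^3)
#' derive from the affine, so the grid is the single source of geometric
#' truth.
#'
#' @param shape integer vector of length 3, array dimensions.
#' @param spacing numeric vector of length 3, voxel spacing in mm per axis;
#'   must be strictly positive. Ignored when `affine` is supplied.
#' @param origin world coordinate (mm) of voxel (0,0,0); default the origin.
#' @param affine optional 4x4 voxel-to-world matrix overriding
#'   `spacing`/`origin`; must be invertible.
#' @return an object of class `voxel_grid` with elements `shape` and `affine`.
#' @examples
#' g <- voxel_grid(c(64, 64, 16), spacing = c(1.2, 1.2, 4.8))
#' voxel_volume(g)  # 6.912 mm^3
#' @export
voxel_grid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("`shape` must be three positive integers", call. = FALSE)
  if (is.null(affine)) {
    spacing <- as.numeric(spacing)
    if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
      stop("`spacing` must be three strictly positive values (mm)",
           call. = FALSE)
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- as.numeric(origin)
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L)))
      stop("`affine` must be a 4x4 matrix", call. = FALSE)
    if (abs(det(affine)) < .Machine$double.eps)
      stop("`affine` must be invertible", call. = FALSE)
  }
  structure(list(shape = shape, affine = affine), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("voxel_grid:", paste(x$shape, collapse = " x "),
      "| spacing", paste(signif(grid_spacing(x), 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' Per-axis voxel spacing of a grid, in mm
#' @param grid a `voxel_grid`.
#' @return numeric vector of length 3 (column norms of the affine).
#' @export
grid_spacing <- function(grid) {
  sqrt(colSums(grid$affine[1:3, 1:3]^2))
}

#' Volume of one voxel, in mm^3
#' @param grid a `voxel_grid`.
#' @export
voxel_volume <- function(grid) {
  abs(det(grid$affine[1:3, 1:3]))
}

#' Test whether two voxel grids are compatible
#'
#' Voxelwise operations (ADC from two b-values, mask intersection, persisting
#' subvolumes) are only meaningful on a shared grid. Two grids match when
#' their shapes are equal and their affines agree element-wise within `tol`
#' millimetres. The relation is reflexive and symmetric.
#'
#' @param a,b `voxel_grid` objects.
#' @param tol tolerance on affine entries, mm. Default `1e-3`.
#' @return `TRUE` or `FALSE`.
#' @export
check_same_grid <- function(a, b, tol = 1e-3) {
  stopifnot(inherits(a, "voxel_grid"), inherits(b, "voxel_grid"))
  all(a$shape == b$shape) && all(abs(a$affine - b$affine) <= tol)
}

assert_same_grid <- function(a, b, what = "inputs", tol = 1e-3) {
  if (!check_same_grid(a, b, tol))
    stop(what, " are not on the same voxel grid", call. = FALSE)
  invisible(TRUE)
}

#' Construct a region-of-interest mask
#'
#' Wraps a logical indicator array with its grid and identifying metadata
#' (patient, tumor label, imaging timepoint). An empty mask is legal; several
#' operations reject it later where a metric would be undefined.
#'
#' @param mask logical (or 0/1) array matching `grid$shape`.
#' @param grid a `voxel_grid`.
#' @param label tumor label, conventionally `"primary"` or `"nodal-<k>"`.
#' @param patient patient identifier.
#' @param timepoint `"preRT"` or `"wk2"`.
#' @return an object of class `roi_mask`.
#' @export
roi_mask <- function(mask, grid, label = "primary", patient = NA_character_,
                     timepoint = "preRT") {
  stopifnot(inherits(grid, "voxel_grid"))
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!all(dim(mask) == grid$shape))
    stop("mask shape does not match grid shape", call. = FALSE)
  if (anyNA(mask))
    stop("mask must not contain NA", call. = FALSE)
  structure(list(mask = mask, grid = grid, label = label,
                 patient = patient, timepoint = timepoint),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask '%s' (%s, %s): %d voxels, %.3f cm^3\n",
              x$label, x$patient, x$timepoint, sum(x$mask), mask_volume(x)))
  invisible(x)
}

#' Volume of a mask in cm^3
#'
#' Voxel count times the voxel volume from the grid affine, converted from
#' mm^3 to cm^3.
#' @param roi an `roi_mask`.
#' @export
mask_volume <- function(roi) {
  stopifnot(inherits(roi, "roi_mask"))
  sum(roi$mask) * voxel_volume(roi$grid) / 1000
}

#' Voxelwise union of two masks on one grid
#' @param a,b `roi_mask` objects on the same grid.
#' @param label label for the result.
#' @keywords internal
mask_union <- function(a, b, label = "union") {
  assert_same_grid(a$grid, b$grid, "masks")
  roi_mask(a$mask | b$mask, a$grid, label = label,
           patient = a$patient, timepoint = a$timepoint)
}
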