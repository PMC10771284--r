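#' Construct a diffusion-weighted volume
#'
#' One signal volume at one diffusion weighting (b-value). Signal is in
#' arbitrary scanner units; only ratios between the two b-values matter for
#' ADC computation.
#'
#' @param values numeric 3-D array of signal intensities.
#' @param b_value diffusion weighting in s/mm^2 (>= 0).
#' @param grid a [voxel_grid()].
#' @param timepoint `"preRT"` or `"wk2"`.
#' @return an object of class `dwi_volume`.
#' @export
dwi_volume <- function(values, b_value, grid, timepoint = "preRT") {
  stopifnot(inherits(grid, "voxel_grid"))
  values <- array(as.numeric(values), dim = dim(values))
  if (!all(dim(values) == grid$shape))
    stop("values shape does not match grid shape", call. = FALSE)
  if (!is.numeric(b_value) || length(b_value) != 1L || b_value < 0)
    stop("b_value must be a single non-negative number (s/mm^2)",
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("signal values must be finite", call. = FALSE)
  structure(list(values = values, b_value = b_value, grid = grid,
                 timepoint = timepoint), class = "dwi_volume")
}

#' Construct an ADC map
#'
#' Voxelwise apparent diffusion coefficient in um^2/ms (equivalently
#' 1e-3 mm^2/s) with an explicit validity indicator. Invalid voxels (from
#' non-positive signal or noise-driven negative estimates) carry `NA` in
#' `values` and `FALSE` in `valid` — they are flagged, never silently zeroed.
#'
#' @param values numeric 3-D array, um^2/ms; `NA` where invalid.
#' @param valid logical 3-D array.
#' @param grid a [voxel_grid()].
#' @param timepoint `"preRT"` or `"wk2"`.
#' @return an object of class `adc_map`.
#' @export
adc_map <- function(values, valid, grid, timepoint = "preRT") {
  stopifnot(inherits(grid, "voxel_grid"))
  values <- array(as.numeric(values), dim = dim(values))
  valid <- array(as.logical(valid), dim = dim(valid))
  if (!all(dim(values) == grid$shape) || !all(dim(valid) == grid$shape))
    stop("values/valid shape does not match grid shape", call. = FALSE)
  if (any(!is.finite(values[valid])) || any(values[valid] < 0))
    stop("valid ADC voxels must be finite and non-negative", call. = FALSE)
  values[!valid] <- NA_real_
  structure(list(values = values, valid = valid, grid = grid,
                 timepoint = timepoint), class = "adc_map")
}

#' @export
print.adc_map <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("adc_map (%s): %s, %d/%d valid voxels, range %.3f-%.3f um^2/ms\n",
              x$timepoint, paste(x$grid$shape, collapse = "x"),
              sum(x$valid), prod(x$grid$shape),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Compute an ADC map from two b-value volumes
#'
#' Assumes monoexponential signal decay S(b) = S0 exp(-b ADC). With exactly
#' two weightings the closed form is
#' ADC = ln(S_low / S_high) / (b_high - b_low), here converted from mm^2/s to
#' um^2/ms (factor 1000). Using a lower b-value of ~50 s/mm^2 rather than 0
#' suppresses the perfusion (pseudo-diffusion) contribution to the estimate.
#'
#' Voxels with non-positive signal at either weighting, and voxels where
#' S_high > S_low (a negative ADC estimate, arising from noise), are marked
#' invalid rather than clipped: clipping to zero would inflate the low-ADC
#' tail that the histogram analysis depends on.
#'
#' @param low `dwi_volume` at the lower b-value (e.g. 50 s/mm^2).
#' @param high `dwi_volume` at the higher b-value (e.g. 800 s/mm^2).
#' @return an [adc_map()] in um^2/ms on the shared grid.
#' @examples
#' g <- voxel_grid(c(2, 2, 2))
#' lo <- dwi_volume(array(1000, c(2, 2, 2)), 50, g)
#' hi <- dwi_volume(array(1000 * exp(-0.9), c(2, 2, 2)), 800, g)
#' compute_adc(lo, hi)$values[1]  # 1.2 um^2/ms
#' @export
compute_adc <- function(low, high) {
  stopifnot(inherits(low, "dwi_volume"), inherits(high, "dwi_volume"))
  if (low$b_value >= high$b_value)
    stop("low$b_value must be strictly less than high$b_value", call. = FALSE)
  assert_same_grid(low$grid, high$grid, "the two DWI volumes")
  db <- high$b_value - low$b_value
  s_lo <- low$values
  s_hi <- high$values
  ok <- s_lo > 0 & s_hi > 0 & s_hi <= s_lo
  vals <- array(NA_real_, dim = low$grid$shape)
  vals[ok] <- log(s_lo[ok] / s_hi[ok]) / db * 1000  # mm^2/s -> um^2/ms
  adc_map(vals, ok, low$grid, timepoint = low$timepoint)
}

# Continuous (0-based) source-voxel coordinates of every target voxel centre.
source_coords <- function(src_grid, tgt_grid) {
  shp <- tgt_grid$shape
  idx <- as.matrix(expand.grid(i = seq_len(shp[1]) - 1,
                               j = seq_len(shp[2]) - 1,
                               k = seq_len(shp[3]) - 1))
  m <- solve(src_grid$affine) %*% tgt_grid$affine
  xyz <- cbind(idx, 1) %*% t(m)
  xyz[, 1:3, drop = FALSE]
}

#' Resample an ADC map onto a target grid
#'
#' Trilinear interpolation of ADC values through the two affines (the typical
#' use is reformatting the diffusion-space map onto the anatomical grid the
#' GTVs were contoured on). A target voxel is valid only when all eight
#' contributing source voxels are in the field of view and valid — validity
#' never interpolates. Masks should be resampled with
#' [resample_mask_to_grid()] (nearest neighbour) instead.
#'
#' @param map an [adc_map()].
#' @param target a [voxel_grid()].
#' @return an [adc_map()] on `target`. If part of the target lies outside the
#'   source field of view a coverage warning is raised and those voxels are
#'   invalid.
#' @export
resample_to_grid <- function(map, target) {
  stopifnot(inherits(map, "adc_map"), inherits(target, "voxel_grid"))
  if (check_same_grid(map$grid, target))
    return(adc_map(map$values, map$valid, target, timepoint = map$timepoint))
  xyz <- source_coords(map$grid, target)
  shp <- map$grid$shape
  f <- floor(xyz)
  w <- xyz - f
  inside <- f[, 1] >= 0 & f[, 2] >= 0 & f[, 3] >= 0 &
    f[, 1] <= shp[1] - 1 & f[, 2] <= shp[2] - 1 & f[, 3] <= shp[3] - 1 &
    (f[, 1] + (w[, 1] > 0)) <= shp[1] - 1 &
    (f[, 2] + (w[, 2] > 0)) <= shp[2] - 1 &
    (f[, 3] + (w[, 3] > 0)) <= shp[3] - 1
  n <- nrow(xyz)
  out <- rep(NA_real_, n)
  ok <- rep(FALSE, n)
  if (any(inside)) {
    fi <- f[inside, , drop = FALSE]
    wi <- w[inside, , drop = FALSE]
    acc <- rep(0, sum(inside))
    all_valid <- rep(TRUE, sum(inside))
    vals <- map$values
    vld <- map$valid
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- (if (dx) wi[, 1] else 1 - wi[, 1]) *
            (if (dy) wi[, 2] else 1 - wi[, 2]) *
            (if (dz) wi[, 3] else 1 - wi[, 3])
      ii <- pmin(fi[, 1] + dx, shp[1] - 1)
      jj <- pmin(fi[, 2] + dy, shp[2] - 1)
      kk <- pmin(fi[, 3] + dz, shp[3] - 1)
      lin <- 1 + ii + shp[1] * (jj + shp[2] * kk)
      contributes <- wt > 0
      all_valid <- all_valid & (!contributes | vld[lin])
      v <- vals[lin]
      v[!contributes] <- 0  # zero-weight neighbours may be NA
      acc <- acc + wt * v
    }
    acc[!all_valid] <- NA_real_
    out[inside] <- acc
    ok[inside] <- all_valid
  }
  if (!all(inside))
    warning(sum(!inside),
            " target voxels fall outside the source field of view",
            call. = FALSE)
  adc_map(array(out, dim = target$shape), array(ok, dim = target$shape),
          target, timepoint = map$timepoint)
}

#' Resample a mask onto a target grid (nearest neighbour)
#'
#' @param roi an [roi_mask()].
#' @param target a [voxel_grid()].
#' @return an [roi_mask()] on `target`; voxels mapping outside the source
#'   field of view are background.
#' @export
resample_mask_to_grid <- function(roi, target) {
  stopifnot(inherits(roi, "roi_mask"), inherits(target, "voxel_grid"))
  if (check_same_grid(roi$grid, target))
    return(roi_mask(roi$mask, target, label = roi$label,
                    patient = roi$patient, timepoint = roi$timepoint))
  xyz <- round(source_coords(roi$grid, target))
  shp <- roi$grid$shape
  inside <- xyz[, 1] >= 0 & xyz[, 2] >= 0 & xyz[, 3] >= 0 &
    xyz[, 1] <= shp[1] - 1 & xyz[, 2] <= shp[2] - 1 & xyz[, 3] <= shp[3] - 1
  out <- rep(FALSE, nrow(xyz))
  lin <- 1 + xyz[inside, 1] + shp[1] * (xyz[inside, 2] + shp[2] * xyz[inside, 3])
  out[inside] <- roi$mask[lin]
  roi_mask(array(out, dim = target$shape), target, label = roi$label,
           patient = roi$patient, timepoint = roi$timepoint)
}

#' Remove gross necrosis from a GTV mask
#'
#' Necrotic and cystic regions approach free-water diffusivity
#' (~3.0 um^2/ms at body temperature). Voxels at or above `ceiling` — by
#' default 2.7 um^2/ms, i.e. 10% below free water — are excluded from the
#' analysis mask, as are voxels with no valid ADC estimate. The comparison is
#' strictly below the ceiling.
#'
#' @param adc an [adc_map()].
#' @param roi an [roi_mask()] on the same grid.
#' @param ceiling exclusion ceiling in um^2/ms. Default
#'   `adc_defaults()$necrosis_ceiling` (2.7).
#' @return the analysis `roi_mask`: `roi` intersected with
#'   `{valid ADC < ceiling}`. Always a subset of `roi`; an empty input gives
#'   an empty output without error.
#' @export
exclude_necrosis <- function(adc, roi, ceiling = adc_defaults()$necrosis_ceiling) {
  stopifnot(inherits(adc, "adc_map"), inherits(roi, "roi_mask"))
  assert_same_grid(adc$grid, roi$grid, "ADC map and mask")
  keep <- roi$mask & adc$valid & !is.na(adc$values) & adc$values < ceiling
  keep[is.na(keep)] <- FALSE
  roi_mask(keep, roi$grid, label = roi$label, patient = roi$patient,
           timepoint = roi$timepoint)
}
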