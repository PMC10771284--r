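#' Construct a blood-volume map
#'
#' Perfusion blood volume per voxel in ml/100g (from dynamic
#' contrast-enhanced MRI; its computation is upstream of this package).
#'
#' @param values numeric 3-D array, ml/100g; `NA` marks invalid voxels.
#' @param grid a [voxel_grid()].
#' @param timepoint `"preRT"` or `"wk2"`.
#' @return an object of class `bv_map` with `values`, `valid`, `grid`,
#'   `timepoint`.
#' @export
bv_map <- function(values, grid, timepoint = "preRT") {
  stopifnot(inherits(grid, "voxel_grid"))
  values <- array(as.numeric(values), dim = dim(values))
  if (!all(dim(values) == grid$shape))
    stop("values shape does not match grid shape", call. = FALSE)
  valid <- is.finite(values)
  if (any(values[valid] < 0))
    stop("valid blood-volume voxels must be non-negative", call. = FALSE)
  structure(list(values = values, valid = valid, grid = grid,
                 timepoint = timepoint), class = "bv_map")
}

#' Persisting low-value subvolume across two timepoints
#'
#' A voxel "persists low" when its value is strictly below `threshold` both
#' pre-RT and after 20 Gy (week 2). Implemented as the voxelwise
#' intersection roi & {pre < thr} & {wk2 < thr} on the co-registered grid; a
#' voxel with an invalid estimate at either timepoint is excluded.
#'
#' @param map_pre,map_wk2 [adc_map()] or [bv_map()] objects at the two
#'   timepoints, co-registered with `roi`.
#' @param roi the [roi_mask()] to search within (typically the union of all
#'   GTVs).
#' @param threshold strict upper bound in the map's unit (um^2/ms for ADC,
#'   ml/100g for blood volume).
#' @return an [roi_mask()], always a subset of `roi`.
#' @export
persisting_low_subvolume <- function(map_pre, map_wk2, roi, threshold) {
  stopifnot(inherits(roi, "roi_mask"))
  assert_same_grid(map_pre$grid, roi$grid, "pre-RT map and roi")
  assert_same_grid(map_wk2$grid, roi$grid, "week-2 map and roi")
  low <- function(m) {
    sel <- m$valid & m$values < threshold
    sel[is.na(sel)] <- FALSE
    sel
  }
  roi_mask(roi$mask & low(map_pre) & low(map_wk2), roi$grid,
           label = paste0(roi$label, "-persist"),
           patient = roi$patient, timepoint = "wk2")
}

#' Build the adaptive boost target and apply the eligibility rule
#'
#' The boost target is the voxelwise union of the persisting low
#' blood-volume subvolume (BV < 7.64 ml/100g at both timepoints) and the
#' persisting low-ADC subvolume (ADC < 1.2 um^2/ms at both timepoints). If
#' the union is smaller than `min_volume` (default 1 cm^3) the patient is
#' not boosted and is flagged for the observation arm.
#'
#' @param low_bv_persist,low_adc_persist [roi_mask()] objects on one grid,
#'   from [persisting_low_subvolume()].
#' @param min_volume eligibility floor in cm^3.
#' @return an object of class `boost_target`: `mask` (the union
#'   `roi_mask`), `volume` (cm^3), `eligible` (volume >= min_volume), and
#'   `provenance` (which of BV/ADC contributed voxels).
#' @export
build_boost_target <- function(low_bv_persist, low_adc_persist,
                               min_volume = adc_defaults()$boost_min_volume) {
  stopifnot(inherits(low_bv_persist, "roi_mask"),
            inherits(low_adc_persist, "roi_mask"))
  assert_same_grid(low_bv_persist$grid, low_adc_persist$grid,
                   "BV and ADC persisting masks")
  union <- roi_mask(low_bv_persist$mask | low_adc_persist$mask,
                    low_bv_persist$grid, label = "boost-target",
                    patient = low_bv_persist$patient, timepoint = "wk2")
  vol <- mask_volume(union)
  structure(list(mask = union,
                 volume = vol,
                 eligible = vol >= min_volume,
                 provenance = c(bv = any(low_bv_persist$mask),
                                adc = any(low_adc_persist$mask))),
            class = "boost_target")
}

#' @export
print.boost_target <- function(x, ...) {
  cat(sprintf("boost_target: %.3f cm^3 -> %s (components: %s)\n",
              x$volume,
              if (x$eligible) "eligible for 80 Gy boost"
              else "below minimum; observation arm",
              paste(names(x$provenance)[x$provenance], collapse = "+")))
  invisible(x)
}
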