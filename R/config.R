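#' Default analysis thresholds and constants
#'
#' Central registry of the tunable constants of the pipeline, each in its
#' working unit:
#' \describe{
#'   \item{b_low, b_high}{diffusion weightings, s/mm^2 (50 and 800).}
#'   \item{necrosis_ceiling}{2.7 um^2/ms — 0.9 x 3.0 um^2/ms, ten percent
#'     below free-water diffusivity at body temperature; voxels at or above
#'     it are treated as gross necrosis and excluded.}
#'   \item{ladc_threshold}{1.2 um^2/ms — upper bound (strict) of the
#'     low-ADC subvolume TV_LADC.}
#'   \item{bv_threshold}{7.64 ml/100g — upper bound (strict) of low blood
#'     volume for the boost-target rule.}
#'   \item{boost_min_volume}{1.0 cm^3 — minimum union subvolume for boost
#'     eligibility; smaller targets route the patient to observation.}
#'   \item{bin_width, hist_max}{ADC histogram binning: width 0.1 um^2/ms over
#'     \[0, 2.7), 27 bins.}
#'   \item{unimodal_sep_factor, unimodal_amp_ratio, unimodal_gof_factor}{
#'     operational rule for declaring a histogram single-Gaussian-like:
#'     peaks closer than `sep_factor * max(sigma)`, minor-component
#'     amplitude below `amp_ratio` of the major one, or a single-Gaussian
#'     fit whose Pearson goodness-of-fit statistic already sits within
#'     `gof_factor` times the bin count (i.e. within sampling noise).}
#'   \item{min_fit_voxels}{minimum voxel count for a histogram fit (50).}
#' }
#' @return a named list of defaults.
#' @export
adc_defaults <- function() {
  list(
    b_low = 50, b_high = 800,
    necrosis_ceiling = 2.7,
    ladc_threshold = 1.2,
    bv_threshold = 7.64,
    boost_min_volume = 1.0,
    bin_width = 0.1,
    hist_max = 2.7,
    unimodal_sep_factor = 1.0,
    unimodal_amp_ratio = 0.05,
    unimodal_gof_factor = 3.0,
    min_fit_voxels = 50L
  )
}

#' Load analysis configuration from YAML
#'
#' Reads a YAML file of threshold overrides and merges it over
#' [adc_defaults()]. Unknown keys are rejected to catch typos.
#'
#' @param path YAML file; `NULL` returns the defaults unchanged.
#' @return named list with the same keys as [adc_defaults()].
#' @export
read_config <- function(path = NULL) {
  cfg <- adc_defaults()
  if (is.null(path)) return(cfg)
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files", call. = FALSE)
  got <- yaml::read_yaml(path)
  unknown <- setdiff(names(got), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(got)] <- got
  cfg
}
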