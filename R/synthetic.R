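#' Specification for a synthetic DWI phantom
#'
#' Describes a digital phantom on the acquisition geometry of the pipeline:
#' ~1.2 x 1.2 x 4.8 mm voxels, diffusion weightings 50 and 800 s/mm^2.
#' Tumor voxels draw their true ADC from a two-component Gaussian mixture
#' (the cellularity-dominated low component and stroma-dominated high
#' component), truncated to \[0.2, 2.6\] um^2/ms so the mixture never
#' collides with the necrosis ceiling; a configurable fraction of voxels is
#' necrotic instead, with ADC ~ Uniform(2.7, 3.0). Background tissue sits at
#' ADC 0.8-1.1. Component means default to typical pre-treatment values for
#' locally advanced head and neck tumors (mu_L 1.08, mu_H 1.67 um^2/ms).
#'
#' @param shape,spacing grid geometry; defaults 64 x 64 x 16 at
#'   1.2 x 1.2 x 4.8 mm.
#' @param tumors list of tumors, each `list(center=, radii=, label=)` in
#'   0-based voxel-index units; default one primary ellipsoid and one node.
#' @param mu_L,mu_H,sigma_L,sigma_H,weight_L mixture parameters (um^2/ms;
#'   `weight_L` in \[0, 1\]).
#' @param necrosis_fraction fraction of tumor voxels drawn from the
#'   free-water-like necrosis component.
#' @param S0 unweighted signal level (arbitrary units).
#' @param noise_sd additive zero-mean Gaussian signal noise; 0 keeps the
#'   two-point ADC inversion exact.
#' @param b_low,b_high diffusion weightings, s/mm^2.
#' @param seed integer seed; the generator is fully reproducible.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64, 64, 16), spacing = c(1.2, 1.2, 4.8),
                         tumors = list(
                           list(center = c(24, 32, 8), radii = c(12, 10, 5),
                                label = "primary"),
                           list(center = c(48, 32, 8), radii = c(7, 6, 3),
                                label = "nodal-1")),
                         mu_L = 1.08, mu_H = 1.67,
                         sigma_L = 0.15, sigma_H = 0.2, weight_L = 0.5,
                         necrosis_fraction = 0.05,
                         S0 = 1000, noise_sd = 0,
                         b_low = 50, b_high = 800, seed = 1L) {
  stopifnot(weight_L >= 0, weight_L <= 1, mu_L <= mu_H,
            sigma_L > 0, sigma_H > 0, necrosis_fraction >= 0,
            necrosis_fraction <= 1, S0 > 0, noise_sd >= 0)
  for (tu in tumors)
    if (any(unlist(tu$radii) <= 0))
      stop("tumor radii must be positive", call. = FALSE)
  structure(list(shape = shape, spacing = spacing, tumors = tumors,
                 mu_L = mu_L, mu_H = mu_H, sigma_L = sigma_L,
                 sigma_H = sigma_H, weight_L = weight_L,
                 necrosis_fraction = necrosis_fraction, S0 = S0,
                 noise_sd = noise_sd, b_low = b_low, b_high = b_high,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Gaussian draws truncated to [lo, hi] by rejection.
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

ellipsoid_mask <- function(shape, center, radii) {
  if (any(center - radii < 0) || any(center + radii > shape - 1))
    stop("tumor ellipsoid exceeds grid bounds", call. = FALSE)
  idx <- expand.grid(i = seq_len(shape[1]) - 1, j = seq_len(shape[2]) - 1,
                     k = seq_len(shape[3]) - 1)
  d <- ((idx$i - center[1]) / radii[1])^2 +
       ((idx$j - center[2]) / radii[2])^2 +
       ((idx$k - center[3]) / radii[3])^2
  array(d <= 1, dim = shape)
}

signal_from_adc <- function(adc_true, b, S0, noise_sd, shape) {
  s <- S0 * exp(-b * adc_true * 1e-3)  # um^2/ms -> mm^2/s under b in s/mm^2
  if (noise_sd > 0) s <- s + stats::rnorm(length(s), 0, noise_sd)
  array(s, dim = shape)
}

#' Generate a two-b-value DWI phantom pair
#'
#' Draws a true ADC field per the spec, forms noise-free signals
#' S(b) = S0 exp(-b ADC_true) at the two b-values, adds optional Gaussian
#' signal noise, and returns the volumes, the tumor masks, and a truth table
#' from which every downstream metric can be checked without re-derivation.
#'
#' @param spec a [phantom_spec()].
#' @param timepoint timepoint tag for the generated volumes.
#' @return list with `dwi_low`, `dwi_high` ([dwi_volume()]), `masks` (named
#'   list of [roi_mask()]), `grid`, and `truth` (list: `adc_true` array,
#'   `necrotic` logical array, `params` = the spec).
#' @export
generate_dwi_pair <- function(spec, timepoint = "preRT") {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- voxel_grid(spec$shape, spacing = spec$spacing)
  shape <- grid$shape
  with_seed(spec$seed, {
    n <- prod(shape)
    adc_true <- array(stats::runif(n, 0.8, 1.1), dim = shape)
    necrotic <- array(FALSE, dim = shape)
    masks <- list()
    for (tu in spec$tumors) {
      m <- ellipsoid_mask(shape, tu$center, tu$radii)
      nt <- sum(m)
      is_necro <- stats::runif(nt) < spec$necrosis_fraction
      vals <- numeric(nt)
      vals[is_necro] <- stats::runif(sum(is_necro), 2.7, 3.0)
      alive <- sum(!is_necro)
      if (alive > 0) {
        from_l <- stats::runif(alive) < spec$weight_L
        draw <- numeric(alive)
        if (any(from_l))
          draw[from_l] <- rnorm_trunc(sum(from_l), spec$mu_L, spec$sigma_L,
                                      0.2, 2.6)
        if (any(!from_l))
          draw[!from_l] <- rnorm_trunc(sum(!from_l), spec$mu_H, spec$sigma_H,
                                       0.2, 2.6)
        vals[!is_necro] <- draw
      }
      adc_true[m] <- vals
      necrotic[m] <- is_necro
      masks[[tu$label]] <- roi_mask(m, grid, label = tu$label,
                                    patient = "phantom",
                                    timepoint = timepoint)
    }
    lo <- signal_from_adc(adc_true, spec$b_low, spec$S0, spec$noise_sd, shape)
    hi <- signal_from_adc(adc_true, spec$b_high, spec$S0, spec$noise_sd, shape)
    list(dwi_low = dwi_volume(lo, spec$b_low, grid, timepoint),
         dwi_high = dwi_volume(hi, spec$b_high, grid, timepoint),
         masks = masks, grid = grid,
         truth = list(adc_true = adc_true, necrotic = necrotic,
                      params = spec))
  })
}

#' Generate the week-2 (after 20 Gy) DWI pair from a baseline phantom
#'
#' Radiotherapy response raises tumor ADC: the week-2 true ADC is the
#' baseline value plus a systematic shift (default +0.15 um^2/ms) and a
#' small voxelwise jitter, applied to tumor voxels only. The truth table
#' makes the persisting low-ADC mask computable by brute force.
#'
#' @param phantom a [generate_dwi_pair()] result.
#' @param wk2_shift systematic tumor ADC increase, um^2/ms.
#' @param jitter_sd voxelwise jitter SD, um^2/ms.
#' @param seed seed for jitter and signal noise.
#' @return same structure as [generate_dwi_pair()], at `timepoint = "wk2"`.
#' @export
generate_longitudinal <- function(phantom, wk2_shift = 0.15,
                                  jitter_sd = 0.02, seed = 2L) {
  spec <- phantom$truth$params
  grid <- phantom$grid
  shape <- grid$shape
  in_tumor <- Reduce(`|`, lapply(phantom$masks, function(m) m$mask))
  with_seed(seed, {
    adc2 <- phantom$truth$adc_true
    nt <- sum(in_tumor)
    adc2[in_tumor] <- pmax(adc2[in_tumor] + wk2_shift +
                             stats::rnorm(nt, 0, jitter_sd), 0.05)
    lo <- signal_from_adc(adc2, spec$b_low, spec$S0, spec$noise_sd, shape)
    hi <- signal_from_adc(adc2, spec$b_high, spec$S0, spec$noise_sd, shape)
    masks <- lapply(phantom$masks, function(m)
      roi_mask(m$mask, grid, label = m$label, patient = m$patient,
               timepoint = "wk2"))
    list(dwi_low = dwi_volume(lo, spec$b_low, grid, "wk2"),
         dwi_high = dwi_volume(hi, spec$b_high, grid, "wk2"),
         masks = masks, grid = grid,
         truth = list(adc_true = adc2, necrotic = phantom$truth$necrotic,
                      params = spec, wk2_shift = wk2_shift))
  })
}

#' Generate a pair of synthetic blood-volume maps
#'
#' A simple stand-in for DCE-derived perfusion: spatially independent
#' Gaussian blood volume (truncated at zero) with a mild week-2 increase, so
#' persisting low-BV regions arise at realistic rates for the 7.64 ml/100g
#' threshold. This is synthetic plumbing for exercising the boost-target
#' rule, not a perfusion model.
#'
#' @param grid a [voxel_grid()].
#' @param mean_bv,sd_bv Gaussian parameters, ml/100g.
#' @param wk2_shift mean week-2 increase, ml/100g.
#' @param seed integer seed.
#' @return list with `bv_pre` and `bv_wk2` ([bv_map()]).
#' @export
generate_bv_pair <- function(grid, mean_bv = 12, sd_bv = 4, wk2_shift = 1,
                             seed = 3L) {
  stopifnot(inherits(grid, "voxel_grid"))
  n <- prod(grid$shape)
  with_seed(seed, {
    pre <- pmax(stats::rnorm(n, mean_bv, sd_bv), 0)
    wk2 <- pmax(pre + stats::rnorm(n, wk2_shift, sd_bv / 4), 0)
    list(bv_pre = bv_map(array(pre, grid$shape), grid, "preRT"),
         bv_wk2 = bv_map(array(wk2, grid$shape), grid, "wk2"))
  })
}

#' Specification for a synthetic patient cohort
#'
#' Defines a cohort whose event times follow a proportional-hazards model by
#' construction: an exponential baseline hazard multiplied by
#' exp(b_p16 p16 + b_L m I(LAHNSCC) + b_H m I(p16+OPSCC)) where m is the
#' median-split indicator of a continuous imaging metric drawn per patient.
#' Censoring combines exponential dropout with an administrative follow-up
#' horizon. Group sizes default to the 28/51 LAHNSCC / p16+OPSCC split of
#' the cohorts this pipeline targets.
#'
#' @param n_lahnscc,n_opscc patients per p16 group.
#' @param p_boost probability of assignment to the 80 Gy arm.
#' @param metric_mean,metric_sd per-group Gaussian parameters of the
#'   continuous metric, named vectors with entries `LAHNSCC` and `OPSCC`.
#' @param log_hr_p16 true log hazard ratio of p16+OPSCC vs LAHNSCC.
#' @param log_hr_metric_lahnscc,log_hr_metric_opscc true log hazard ratios
#'   of the metric indicator within each group.
#' @param baseline_rate exponential baseline hazard, events per day.
#' @param dropout_rate exponential dropout hazard, per day.
#' @param admin_days administrative follow-up horizon, days.
#' @param event_type_probs probabilities that a progression is local,
#'   regional or distant (named `lp`, `rp`, `dp`; must sum to 1).
#' @param p_simultaneous probability that a progression registers a second
#'   type on the same day (the cohorts modelled contain simultaneous
#'   failures).
#' @param seed integer seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_lahnscc = 28, n_opscc = 51, p_boost = 0.5,
                        metric_mean = c(LAHNSCC = 16, OPSCC = 14),
                        metric_sd = c(LAHNSCC = 8, OPSCC = 8),
                        log_hr_p16 = log(0.3),
                        log_hr_metric_lahnscc = log(4),
                        log_hr_metric_opscc = 0,
                        baseline_rate = 1 / 1500,
                        dropout_rate = 1 / 4000,
                        admin_days = 1095,
                        event_type_probs = c(lp = 0.35, rp = 0.15, dp = 0.5),
                        p_simultaneous = 0.1,
                        seed = 1L) {
  stopifnot(n_lahnscc >= 2, n_opscc >= 2, baseline_rate > 0,
            dropout_rate >= 0, admin_days > 0,
            abs(sum(event_type_probs) - 1) < 1e-9,
            p_simultaneous >= 0, p_simultaneous <= 1)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic cohort with known hazard structure
#'
#' Draws per-patient metrics, dichotomizes them at the in-sample median,
#' simulates progression times from the spec's proportional-hazards model,
#' races them against dropout and the administrative horizon, and assigns
#' each progression a type (local/regional/distant, possibly two types on
#' one day). The output is directly consumable by [derive_endpoint()] and
#' [fit_cox_interaction()], and the truth element carries everything needed
#' to verify recovery.
#'
#' @param spec a [cohort_spec()].
#' @return list with `cohort` (data.frame: `id`, `p16_group`, `arm`,
#'   `p16`, `metric`, `indicator`, `lp_day`, `rp_day`, `dp_day`,
#'   `death_day`, `last_fu_day`) and `truth` (spec parameters, the median
#'   cutpoint, and the latent event/censor times).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_lahnscc + spec$n_opscc
    p16 <- rep(c(0, 1), c(spec$n_lahnscc, spec$n_opscc))
    grp <- ifelse(p16 == 1, "p16+OPSCC", "LAHNSCC")
    arm <- ifelse(stats::runif(n) < spec$p_boost, "80Gy", "70Gy")
    mkey <- ifelse(p16 == 1, "OPSCC", "LAHNSCC")
    metric <- stats::rnorm(n, spec$metric_mean[mkey], spec$metric_sd[mkey])
    ind <- dichotomize_at_median(metric)

    lp <- exp(spec$log_hr_p16 * p16 +
                spec$log_hr_metric_lahnscc * ind * (1 - p16) +
                spec$log_hr_metric_opscc * ind * p16)
    t_event <- stats::rexp(n, rate = spec$baseline_rate * lp)
    t_drop <- if (spec$dropout_rate > 0)
      stats::rexp(n, rate = spec$dropout_rate) else rep(Inf, n)
    t_cens <- pmin(t_drop, spec$admin_days)
    if (all(t_cens < t_event))
      stop("degenerate cohort spec: every patient censored", call. = FALSE)
    has_event <- t_event <= t_cens

    day <- function(x) pmax(round(x, 1), 0.5)
    lp_day <- rp_day <- dp_day <- rep(NA_real_, n)
    type <- sample(names(spec$event_type_probs), n, replace = TRUE,
                   prob = spec$event_type_probs)
    second <- stats::runif(n) < spec$p_simultaneous
    for (i in which(has_event)) {
      t <- day(t_event[i])
      if (type[i] == "lp") lp_day[i] <- t
      if (type[i] == "rp") rp_day[i] <- t
      if (type[i] == "dp") dp_day[i] <- t
      if (second[i]) {
        other <- sample(setdiff(c("lp", "rp", "dp"), type[i]), 1)
        if (other == "lp") lp_day[i] <- t
        if (other == "rp") rp_day[i] <- t
        if (other == "dp") dp_day[i] <- t
      }
    }
    last_fu <- day(pmin(t_event, t_cens))

    cohort <- data.frame(
      id = sprintf("SYN%03d", seq_len(n)),
      p16_group = grp, arm = arm, p16 = p16,
      metric = metric, indicator = as.integer(ind),
      lp_day = lp_day, rp_day = rp_day, dp_day = dp_day,
      death_day = NA_real_, last_fu_day = last_fu,
      stringsAsFactors = FALSE)
    list(cohort = cohort,
         truth = list(spec = spec, cutpoint = attr(ind, "cutpoint"),
                      t_event = t_event, t_censor = t_cens,
                      has_event = has_event, type = type))
  })
}
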