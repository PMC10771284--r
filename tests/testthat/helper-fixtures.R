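# Small constructors used across tests.

with_seed <- adcboost:::with_seed

# An adc_map holding the given values (vector or array); NA marks invalid.
make_adc <- function(values, shape = NULL, spacing = c(1, 1, 1),
                     timepoint = "preRT") {
  if (is.null(shape)) shape <- if (is.array(values)) dim(values)
                               else c(length(values), 1, 1)
  g <- voxel_grid(shape, spacing = spacing)
  v <- array(as.numeric(values), dim = shape)
  adc_map(v, !is.na(v), g, timepoint = timepoint)
}

# A full or indicator mask on the same geometry.
make_mask <- function(shape, spacing = c(1, 1, 1), where = TRUE,
                      label = "primary") {
  g <- voxel_grid(shape, spacing = spacing)
  m <- array(FALSE, dim = shape)
  m[where] <- TRUE
  roi_mask(m, g, label = label)
}

# A histogram built directly from a vector of in-range ADC values.
hist_from_values <- function(v, spacing = c(1, 1, 1)) {
  a <- make_adc(v, spacing = spacing)
  m <- make_mask(c(length(v), 1, 1), spacing = spacing)
  build_histogram(a, m)
}

# Truncated-Gaussian draws (rejection, as in the phantom generator).
draw_trunc <- function(n, mu, s, lo = 0.005, hi = 2.695) {
  v <- stats::rnorm(n, mu, s)
  while (any(bad <- v < lo | v > hi)) v[bad] <- stats::rnorm(sum(bad), mu, s)
  v
}

# Two-component mixture draws on the histogram support.
draw_mixture <- function(n, mu_l, mu_h, s_l, s_h, w_l = 0.5) {
  from_l <- stats::runif(n) < w_l
  v <- numeric(n)
  v[from_l] <- draw_trunc(sum(from_l), mu_l, s_l)
  v[!from_l] <- draw_trunc(sum(!from_l), mu_h, s_h)
  v
}

# One-row cohort record with named day offsets; everything else NA.
cohort_row <- function(id = "P1", p16_group = "LAHNSCC", arm = "70Gy",
                       lp = NA, rp = NA, dp = NA, death = NA, fu = 900) {
  data.frame(id = id, p16_group = p16_group, arm = arm,
             lp_day = as.numeric(lp), rp_day = as.numeric(rp),
             dp_day = as.numeric(dp), death_day = as.numeric(death),
             last_fu_day = as.numeric(fu), stringsAsFactors = FALSE)
}
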