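#' Mean ADC within a mask
#'
#' Arithmetic mean of the valid ADC values in the analysis mask (necrosis
#' already excluded upstream).
#'
#' @param adc an [adc_map()].
#' @param mask an [roi_mask()] on the same grid.
#' @return mean ADC in um^2/ms.
#' @export
mean_adc <- function(adc, mask) {
  v <- masked_adc_values(adc, mask)
  if (!length(v))
    stop("mean ADC undefined: no valid voxels in mask", call. = FALSE)
  mean(v)
}

#' Low-ADC subvolume (TV_LADC) in cm^3
#'
#' Volume of the mask voxels whose ADC is strictly below `threshold`
#' (default 1.2 um^2/ms). High cellularity depresses ADC, so this subvolume
#' is read as the densely cellular tumor burden. An empty result is 0, not
#' an error.
#'
#' @param adc an [adc_map()].
#' @param mask an [roi_mask()] on the same grid.
#' @param threshold um^2/ms; voxels at exactly the threshold are not counted.
#' @return subvolume in cm^3.
#' @export
low_adc_subvolume <- function(adc, mask,
                              threshold = adc_defaults()$ladc_threshold) {
  v <- masked_adc_values(adc, mask)
  sum(v < threshold) * voxel_volume(mask$grid) / 1000
}

#' Bin the in-mask ADC values into the standard histogram
#'
#' Fixed support \[0, 2.7) with bin width 0.1 um^2/ms (27 bins), left-closed
#' right-open, so the bin scheme is identical across tumors and group
#' averaging is well defined. Values at or above 2.7 must have been removed
#' by [exclude_necrosis()]; encountering one here is an error rather than a
#' silent drop.
#'
#' @param adc an [adc_map()].
#' @param mask an [roi_mask()] on the same grid; must be nonempty.
#' @param bin_width bin width in um^2/ms (must divide `hist_max` evenly).
#' @param hist_max upper edge of the support, um^2/ms.
#' @return an object of class `adc_histogram` with `bin_edges`, `counts`,
#'   `total` and `voxel_volume` (mm^3).
#' @export
build_histogram <- function(adc, mask, bin_width = adc_defaults()$bin_width,
                            hist_max = adc_defaults()$hist_max) {
  v <- masked_adc_values(adc, mask)
  if (!length(v))
    stop("histogram undefined: no valid voxels in mask", call. = FALSE)
  nbin <- round(hist_max / bin_width)
  if (abs(nbin * bin_width - hist_max) > 1e-9)
    stop("bin_width must evenly divide hist_max", call. = FALSE)
  if (any(v < 0 | v >= hist_max))
    stop("ADC values outside [0, ", hist_max,
         ") in mask; run exclude_necrosis first", call. = FALSE)
  idx <- pmin(floor(v / bin_width), nbin - 1) + 1  # left-closed, right-open
  counts <- tabulate(idx, nbins = nbin)
  structure(list(bin_edges = seq(0, hist_max, by = bin_width),
                 counts = as.integer(counts),
                 total = length(v),
                 voxel_volume = voxel_volume(mask$grid)),
            class = "adc_histogram")
}

#' @export
print.adc_histogram <- function(x, ...) {
  cat(sprintf("adc_histogram: %d voxels in %d bins of width %.2f um^2/ms\n",
              x$total, length(x$counts), diff(x$bin_edges[1:2])))
  invisible(x)
}

bin_centers <- function(hist) {
  e <- hist$bin_edges
  (e[-1] + e[-length(e)]) / 2
}

# Unnormalized Gaussian shape; amplitude is carried separately in counts.
gauss_shape <- function(x, mu, sigma) exp(-(x - mu)^2 / (2 * sigma^2))

# Sum of squared errors of a one- or two-component Gaussian model against
# bin counts. Parameters outside their domain earn a graded penalty so the
# simplex can find its way back.
sse_gaussians <- function(par, centers, counts) {
  k <- length(par) / 3
  pen <- 0
  fit <- numeric(length(centers))
  for (i in seq_len(k)) {
    mu <- par[3 * i - 2]; sigma <- par[3 * i - 1]; A <- par[3 * i]
    if (sigma < 1e-3) { pen <- pen + (1e-3 - sigma); sigma <- 1e-3 }
    if (A < 0) { pen <- pen + (-A); A <- 0 }
    if (mu < -0.5) pen <- pen + (-0.5 - mu)
    if (mu > 3.2) pen <- pen + (mu - 3.2)
    fit <- fit + A * gauss_shape(centers, mu, sigma)
  }
  sum((counts - fit)^2) * (1 + pen) + pen * sum(counts^2)
}

# Weighted quantile of bin centers, used to place starting values.
hist_quantile <- function(hist, p) {
  cs <- cumsum(hist$counts) / hist$total
  centers <- bin_centers(hist)
  centers[which(cs >= p)[1]]
}

fit_single_gaussian <- function(hist) {
  centers <- bin_centers(hist)
  counts <- hist$counts
  mu0 <- sum(centers * counts) / sum(counts)
  s0 <- sqrt(max(sum(counts * (centers - mu0)^2) / sum(counts), 1e-4))
  a0 <- max(counts)
  best <- NULL
  for (start in list(c(mu0, s0, a0),
                     c(hist_quantile(hist, 0.5), max(s0 / 2, 0.05), a0))) {
    res <- stats::optim(start, sse_gaussians, centers = centers,
                        counts = counts, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || res$value < best$value) best <- res
  }
  list(mu = best$par[1], sigma = abs(best$par[2]), A = max(best$par[3], 0),
       residual = best$value)
}

#' Decide whether a two-component fit is really single-Gaussian-like
#'
#' The decomposition is declared unimodal when any of three conditions
#' holds: (a) the fitted peaks are closer than `sep_factor` times the
#' larger component width; (b) the smaller amplitude is below `amp_ratio`
#' of the larger — the second component is unresolvable or negligible; or
#' (c), when the histogram is supplied, a single-Gaussian fit already
#' explains the counts to within sampling noise: its Pearson statistic
#' sum_b (n_b - fit_b)^2 / max(fit_b, 1) is at most `gof_factor` times the
#' number of bins (for Poisson-distributed counts the statistic of an
#' adequate model is on the order of the bin count, so a value near it
#' means a second component would only be fitting noise or mild skew, not
#' structure). In the unimodal case the convention is to refit a single
#' Gaussian and report it as both components with the amplitude split
#' 50/50 (see [fit_bimodal()]).
#'
#' @param fit a candidate `bimodal_fit` (two converged components).
#' @param hist the fitted `adc_histogram`; enables rule (c).
#' @param sep_factor,amp_ratio,gof_factor rule constants; defaults from
#'   [adc_defaults()].
#' @return `TRUE` if the histogram should be treated as unimodal.
#' @export
detect_unimodality <- function(fit, hist = NULL,
                               sep_factor = adc_defaults()$unimodal_sep_factor,
                               amp_ratio = adc_defaults()$unimodal_amp_ratio,
                               gof_factor = adc_defaults()$unimodal_gof_factor) {
  sep <- abs(fit$H$mu - fit$L$mu)
  too_close <- sep < sep_factor * max(fit$L$sigma, fit$H$sigma)
  amps <- c(fit$L$A, fit$H$A)
  negligible <- (max(amps) <= 0) || (min(amps) / max(amps) < amp_ratio)
  single_adequate <- FALSE
  if (!is.null(hist)) {
    single <- fit_single_gaussian(hist)
    pred <- single$A * gauss_shape(bin_centers(hist), single$mu, single$sigma)
    chi2 <- sum((hist$counts - pred)^2 / pmax(pred, 1))
    single_adequate <- chi2 <= gof_factor * length(hist$counts)
  }
  isTRUE(too_close) || isTRUE(negligible) || isTRUE(single_adequate)
}

#' Two-Gaussian decomposition of an ADC histogram
#'
#' Models the binned ADC distribution as the sum of a low- and a high-ADC
#' Gaussian component — cellularity-dominated and stroma/edema-dominated
#' tissue respectively — and minimizes the sum of squared bin errors
#'
#'   sum_b \[ n_b - A_L g(c_b; mu_L, s_L) - A_H g(c_b; mu_H, s_H) \]^2
#'
#' over bin centers c_b with a multi-start Nelder-Mead simplex. Amplitudes
#' are in counts (the fit targets raw counts, not densities). Starting
#' points place the two means at the 25th/75th percentile of the in-mask
#' distribution with interquartile-derived widths; additional restarts
#' jitter these, and one restart duplicates the best single-Gaussian
#' solution so the two-component residual can never end up worse than the
#' nested one-component fit. Components are relabelled after fitting so that
#' `L$mu <= H$mu`.
#'
#' If the result looks single-Gaussian-like under [detect_unimodality()],
#' the single-component refit is reported as both L and H (same mu and
#' sigma) with the amplitude split 50% each, and `unimodal = TRUE`.
#'
#' The fit is deterministic given `(hist, restarts, seed)`.
#'
#' @param hist an [build_histogram()] result.
#' @param restarts number of Nelder-Mead restarts (default 8).
#' @param seed integer seed for the restart jitter.
#' @param min_voxels minimum total count required for a meaningful fit.
#' @param sep_factor,amp_ratio,gof_factor unimodality rule constants,
#'   passed to [detect_unimodality()].
#' @return an object of class `bimodal_fit`: components `L` and `H` (each
#'   `mu`, `sigma`, `A`), `unimodal`, `residual` (sum of squared bin
#'   errors), and `converged`.
#' @export
fit_bimodal <- function(hist, restarts = 8, seed = 1L,
                        min_voxels = adc_defaults()$min_fit_voxels,
                        sep_factor = adc_defaults()$unimodal_sep_factor,
                        amp_ratio = adc_defaults()$unimodal_amp_ratio,
                        gof_factor = adc_defaults()$unimodal_gof_factor) {
  stopifnot(inherits(hist, "adc_histogram"))
  if (hist$total < min_voxels)
    stop("bimodal fit undefined: only ", hist$total,
         " voxels (minimum ", min_voxels, ")", call. = FALSE)
  centers <- bin_centers(hist)
  counts <- hist$counts

  single <- fit_single_gaussian(hist)

  q25 <- hist_quantile(hist, 0.25)
  q75 <- hist_quantile(hist, 0.75)
  s0 <- min(max((q75 - q25) / 2, 0.05), 0.5)
  a0 <- max(counts) * 0.6

  starts <- list(c(q25, s0, a0, q75, s0, a0),
                 with(single, c(mu, sigma, A / 2, mu + 1e-3, sigma, A / 2)))
  n_extra <- max(restarts - length(starts), 0)
  if (n_extra > 0) {
    jit <- with_seed(seed, matrix(stats::runif(n_extra * 6, -1, 1), n_extra))
    for (r in seq_len(n_extra)) {
      starts[[length(starts) + 1]] <-
        c(q25 + 0.25 * jit[r, 1], s0 * 2^jit[r, 2], a0 * 2^jit[r, 3],
          q75 + 0.25 * jit[r, 4], s0 * 2^jit[r, 5], a0 * 2^jit[r, 6])
    }
  }

  best <- NULL
  any_conv <- FALSE
  for (start in starts) {
    res <- stats::optim(start, sse_gaussians, centers = centers,
                        counts = counts, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-12))
    any_conv <- any_conv || res$convergence == 0
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (!any_conv)
    warning("Nelder-Mead did not converge in any restart; ",
            "reporting best solution found", call. = FALSE)

  p <- best$par
  comps <- list(list(mu = p[1], sigma = abs(p[2]), A = max(p[3], 0)),
                list(mu = p[4], sigma = abs(p[5]), A = max(p[6], 0)))
  ord <- order(c(comps[[1]]$mu, comps[[2]]$mu))
  fit <- structure(list(L = comps[[ord[1]]], H = comps[[ord[2]]],
                        unimodal = FALSE, residual = best$value,
                        converged = any_conv),
                   class = "bimodal_fit")

  if (detect_unimodality(fit, hist, sep_factor, amp_ratio, gof_factor)) {
    comp <- list(mu = single$mu, sigma = single$sigma, A = single$A / 2)
    fit$L <- comp
    fit$H <- comp
    fit$unimodal <- TRUE
    fit$residual <- single$residual
  }
  fit
}

#' @export
print.bimodal_fit <- function(x, ...) {
  cat(sprintf(
    "bimodal_fit%s: mu_L=%.3f (s=%.3f, A=%.1f), mu_H=%.3f (s=%.3f, A=%.1f), SSE=%.1f\n",
    if (x$unimodal) " [unimodal 50/50]" else "",
    x$L$mu, x$L$sigma, x$L$A, x$H$mu, x$H$sigma, x$H$A, x$residual))
  invisible(x)
}

#' Per-tumor scalar ADC summaries
#'
#' Computes the full metric set for one tumor at one timepoint: GTV volume
#' (of the supplied contour), mean ADC, TV_LADC, and the two-Gaussian
#' histogram decomposition — all on the analysis mask after necrosis
#' exclusion.
#'
#' @param adc an [adc_map()].
#' @param roi the contoured GTV as an [roi_mask()] (before necrosis
#'   exclusion; its volume is reported as `gtv_volume`).
#' @param necrosis_ceiling,ladc_threshold thresholds in um^2/ms.
#' @param ... further arguments passed to [fit_bimodal()].
#' @return an object of class `tumor_metrics`: `patient`, `label`,
#'   `timepoint`, `gtv_volume` (cm^3), `mean_adc`, `tv_ladc` (cm^3), `fit`
#'   (a `bimodal_fit`).
#' @export
tumor_metrics <- function(adc, roi,
                          necrosis_ceiling = adc_defaults()$necrosis_ceiling,
                          ladc_threshold = adc_defaults()$ladc_threshold,
                          ...) {
  analysis <- exclude_necrosis(adc, roi, necrosis_ceiling)
  hist <- build_histogram(adc, analysis)
  structure(list(patient = roi$patient, label = roi$label,
                 timepoint = roi$timepoint,
                 gtv_volume = mask_volume(roi),
                 mean_adc = mean_adc(adc, analysis),
                 tv_ladc = low_adc_subvolume(adc, analysis, ladc_threshold),
                 fit = fit_bimodal(hist, ...)),
            class = "tumor_metrics")
}

#' @export
print.tumor_metrics <- function(x, ...) {
  cat(sprintf(
    "tumor_metrics %s/%s (%s): GTV %.2f cm^3, mean ADC %.3f, TV_LADC %.2f cm^3\n",
    x$patient, x$label, x$timepoint, x$gtv_volume, x$mean_adc, x$tv_ladc))
  print(x$fit)
  invisible(x)
}

#' Flatten tumor metrics to a one-row data frame
#' @param x a `tumor_metrics` object.
#' @param ... unused.
#' @return data.frame with the metrics CSV columns.
#' @export
as.data.frame.tumor_metrics <- function(x, ...) {
  data.frame(patient = x$patient, tumor = x$label, timepoint = x$timepoint,
             gtv_cm3 = x$gtv_volume, mean_adc = x$mean_adc,
             tv_ladc_cm3 = x$tv_ladc,
             mu_L = x$fit$L$mu, sigma_L = x$fit$L$sigma, A_L = x$fit$L$A,
             mu_H = x$fit$H$mu, sigma_H = x$fit$H$sigma, A_H = x$fit$H$A,
             unimodal = x$fit$unimodal, residual = x$fit$residual,
             stringsAsFactors = FALSE)
}

#' Pooled metrics over the total nodal burden
#'
#' Pools the voxels of all nodal GTVs (set union, so overlap is counted
#' once) and computes the same metric set as [tumor_metrics()] on the pooled
#' region, labelled `"nodal-total"`.
#'
#' @param adc an [adc_map()].
#' @param nodal_masks nonempty list of [roi_mask()] objects on the ADC grid.
#' @param ... passed on to [tumor_metrics()].
#' @return a `tumor_metrics` object for the pooled nodal volume.
#' @export
total_nodal_metrics <- function(adc, nodal_masks, ...) {
  if (!length(nodal_masks))
    stop("total nodal metrics undefined: no nodal masks", call. = FALSE)
  pooled <- Reduce(function(a, b) mask_union(a, b), nodal_masks)
  pooled$label <- "nodal-total"
  tumor_metrics(adc, pooled, ...)
}

#' Group-averaged ADC histogram
#'
#' Normalizes each histogram to unit area (density over um^2/ms) and takes
#' the bin-wise arithmetic mean, so every tumor contributes equally
#' regardless of its volume. The average integrates to 1.
#'
#' @param hists nonempty list of `adc_histogram` objects on a common bin
#'   scheme.
#' @return list of class `avg_histogram` with `bin_edges`, `density`, and
#'   `n` (number of histograms averaged).
#' @export
group_average_histogram <- function(hists) {
  if (!length(hists)) stop("no histograms to average", call. = FALSE)
  edges <- hists[[1]]$bin_edges
  for (h in hists)
    if (length(h$bin_edges) != length(edges) ||
        any(abs(h$bin_edges - edges) > 1e-9))
      stop("histograms use different bin schemes", call. = FALSE)
  w <- diff(edges[1:2])
  dens <- vapply(hists, function(h) h$counts / (h$total * w),
                 numeric(length(edges) - 1))
  structure(list(bin_edges = edges, density = rowMeans(dens),
                 n = length(hists)),
            class = "avg_histogram")
}

#' Plot an averaged ADC histogram
#' @param x an `avg_histogram`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.avg_histogram <- function(x, ...) {
  centers <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  graphics::plot(centers, x$density, type = "h", lwd = 6, lend = 1,
                 xlab = expression(ADC ~ (mu * m^2 / ms)),
                 ylab = "mean density", ...)
  invisible(x)
}
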