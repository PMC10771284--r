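.endpoints <- list(
  FFLP   = "lp_day",
  FFLRP  = c("lp_day", "rp_day"),
  FFDP   = "dp_day",
  FFLRDP = c("lp_day", "rp_day", "dp_day")
)

#' Derive a time-to-event dataset for one progression endpoint
#'
#' Endpoints are freedom from local (FFLP), locoregional (FFLRP), distant
#' (FFDP), and locoregional-or-distant (FFLRDP) progression. Time runs from
#' the start of radiotherapy. The event time is the earliest progression of
#' a type targeted by the endpoint; the record is censored at the earliest
#' of any non-targeted progression, death, or last follow-up. A progression
#' occurring on the same day as a censoring cause counts as an event (the
#' cohorts this models contain simultaneous failures).
#'
#' Records with no usable time at all are skipped with a warning, as are
#' records whose derived time is not positive.
#'
#' @param records a `data.frame` (e.g. a [read_cohort()] result) with
#'   columns `id`, `lp_day`, `rp_day`, `dp_day`, `death_day`,
#'   `last_fu_day`; any further columns (group, arm, metrics) are carried
#'   through.
#' @param endpoint one of `"FFLP"`, `"FFLRP"`, `"FFDP"`, `"FFLRDP"`.
#' @return a `data.frame` with the input columns plus `time` (days > 0) and
#'   `event` (0/1), one row per usable patient; attribute `skipped` lists
#'   dropped ids.
#' @export
derive_endpoint <- function(records, endpoint = c("FFLP", "FFLRP", "FFDP",
                                                  "FFLRDP")) {
  endpoint <- match.arg(endpoint)
  targeted <- .endpoints[[endpoint]]
  others <- setdiff(c("lp_day", "rp_day", "dp_day"), targeted)
  censor_cols <- c(others, "death_day", "last_fu_day")

  min_row <- function(cols) {
    m <- as.matrix(records[cols])
    suppressWarnings(apply(m, 1, function(r)
      if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE)))
  }
  t_event <- min_row(targeted)
  t_censor <- min_row(censor_cols)

  event <- !is.na(t_event) & (is.na(t_censor) | t_event <= t_censor)
  time <- ifelse(event, t_event, t_censor)

  usable <- !is.na(time) & time > 0
  if (any(!usable))
    warning(sum(!usable), " record(s) skipped for endpoint ", endpoint,
            ": no usable positive time", call. = FALSE)
  out <- records[usable, , drop = FALSE]
  out$time <- time[usable]
  out$event <- as.integer(event[usable])
  attr(out, "endpoint") <- endpoint
  attr(out, "skipped") <- records$id[!usable]
  out
}

#' Exclude boosted no-evidence-of-disease patients from local endpoints
#'
#' The dose boost is expected to influence local and regional control, so
#' for the locally-targeted endpoints (everything except FFDP) boosted
#' patients who never progressed are removed from the prediction models —
#' their favorable outcome may be a treatment effect, not a marker effect.
#' Boosted patients with any progression are retained, and for FFDP all
#' patients are retained since no boost effect on distant control is
#' expected.
#'
#' @param records cohort `data.frame` with columns `arm`, `lp_day`,
#'   `rp_day`, `dp_day`.
#' @param endpoint endpoint name; `"FFDP"` disables the exclusion.
#' @return the filtered `data.frame`; attribute `n_excluded` records the
#'   count.
#' @export
apply_boost_exclusion <- function(records, endpoint) {
  if (endpoint == "FFDP") {
    attr(records, "n_excluded") <- 0L
    return(records)
  }
  ned <- is.na(records$lp_day) & is.na(records$rp_day) & is.na(records$dp_day)
  drop <- records$arm == "80Gy" & ned
  out <- records[!drop, , drop = FALSE]
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Dichotomize a metric at the cohort median
#'
#' Indicator is 1 when the value is strictly greater than the median of the
#' non-missing values (ties at the median go to the low group). The median
#' must be computed over the analysis cohort after exclusions — pass the
#' filtered values.
#'
#' @param values numeric vector; `NA` allowed and propagated.
#' @return integer vector of 0/1 (NA where the input is NA), with the
#'   median as attribute `cutpoint`.
#' @export
dichotomize_at_median <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2)
    stop("need at least two non-missing values to dichotomize", call. = FALSE)
  med <- stats::median(values[ok])
  out <- ifelse(is.na(values), NA_integer_, as.integer(values > med))
  attr(out, "cutpoint") <- med
  out
}

#' Cox model with a p16-by-metric interaction
#'
#' Fits a proportional-hazards model with group-specific metric slopes,
#'
#'   h(t) = h0(t) exp(b1 p16 + b2 metric I(LAHNSCC) + b3 metric I(p16+OPSCC)),
#'
#' which makes the reported contrasts direct coefficient transforms: the
#' metric effect within LAHNSCC is exp(b2), within p16+OPSCC exp(b3), the
#' difference in effects (the interaction) exp(b3 - b2), and the p16 effect
#' exp(b1). Each is reported with a Wald 95% CI and p-value.
#'
#' Non-convergence or monotone likelihood (e.g. zero events in a stratum,
#' which drives a coefficient to infinity) is flagged in the result rather
#' than silently reported.
#'
#' @param dataset a [derive_endpoint()] result with columns `time`, `event`,
#'   `p16` (1 = p16+OPSCC, 0 = LAHNSCC) and the metric column.
#' @param metric name of the metric column (dichotomized indicator or
#'   continuous).
#' @return an object of class `cox_result`: a `data.frame` with one row per
#'   contrast (`contrast`, `hr`, `ci_low`, `ci_high`, `p`) plus attributes
#'   `flagged` (logical), `diagnostics` (character), and `fit` (the
#'   underlying `coxph` object).
#' @export
fit_cox_interaction <- function(dataset, metric = "metric") {
  stopifnot(all(c("time", "event", "p16", metric) %in% names(dataset)))
  d <- data.frame(time = dataset$time, event = dataset$event,
                  p16 = dataset$p16,
                  x_lahn = dataset[[metric]] * (1 - dataset$p16),
                  x_op = dataset[[metric]] * dataset$p16)
  d <- d[stats::complete.cases(d), , drop = FALSE]

  diagnostics <- character(0)
  for (g in c(0, 1)) {
    if (sum(d$event[d$p16 == g]) == 0)
      diagnostics <- c(diagnostics,
                       sprintf("zero events in p16=%d stratum", g))
  }
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ p16 + x_lahn + x_op,
                    data = d),
    warning = function(w) {
      diagnostics <<- c(diagnostics, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)

  contrast_row <- function(name, est, se) {
    z <- est / se
    data.frame(contrast = name, hr = exp(est),
               ci_low = exp(est - 1.96 * se), ci_high = exp(est + 1.96 * se),
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }
  rows <- rbind(
    contrast_row("p16", beta["p16"], sqrt(V["p16", "p16"])),
    contrast_row("metric_LAHNSCC", beta["x_lahn"],
                 sqrt(V["x_lahn", "x_lahn"])),
    contrast_row("metric_p16+OPSCC", beta["x_op"], sqrt(V["x_op", "x_op"])),
    contrast_row("difference_in_effects", beta["x_op"] - beta["x_lahn"],
                 sqrt(V["x_op", "x_op"] + V["x_lahn", "x_lahn"] -
                        2 * V["x_op", "x_lahn"])))
  rownames(rows) <- NULL

  if (any(abs(beta) > 15) || any(!is.finite(beta)))
    diagnostics <- c(diagnostics, "coefficient diverging (monotone likelihood?)")
  structure(rows, class = c("cox_result", "data.frame"),
            flagged = length(diagnostics) > 0, diagnostics = diagnostics,
            fit = fit)
}

#' @export
print.cox_result <- function(x, ...) {
  df <- as.data.frame(x)
  df$hr <- sprintf("%.2f (%.2f-%.2f)", df$hr, df$ci_low, df$ci_high)
  print(df[c("contrast", "hr", "p")], row.names = FALSE)
  if (isTRUE(attr(x, "flagged")))
    cat("flagged:", paste(attr(x, "diagnostics"), collapse = "; "), "\n")
  invisible(x)
}

#' Benjamini-Hochberg adjustment within declared families
#'
#' Step-up false-discovery-rate control applied separately within each level
#' of `grouping` (one family per endpoint-by-contrast column, mirroring how
#' multiple models of the same endpoint are read together). Adjusted values
#' are monotone within a family and capped at 1.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @param grouping optional family labels, same length; `NULL` treats all
#'   p-values as one family.
#' @return adjusted p-values in the original order.
#' @export
fdr_adjust <- function(pvalues, grouping = NULL) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (is.null(grouping))
    return(stats::p.adjust(pvalues, method = "BH"))
  if (length(grouping) != length(pvalues))
    stop("`grouping` must match `pvalues` in length", call. = FALSE)
  out <- numeric(length(pvalues))
  for (g in unique(grouping)) {
    sel <- grouping == g
    out[sel] <- stats::p.adjust(pvalues[sel], method = "BH")
  }
  out
}

#' Kaplan-Meier curves split by a binary indicator, with log-rank test
#'
#' @param dataset a [derive_endpoint()] result (`time`, `event`).
#' @param indicator 0/1 vector, one per row (e.g. a median split); both
#'   groups must be nonempty.
#' @return list of class `km_split`: `fit` (a `survfit` object with strata
#'   `low`/`high`), `logrank_p`, and `table` (time/surv/group long format).
#' @export
km_by_split <- function(dataset, indicator) {
  stopifnot(all(c("time", "event") %in% names(dataset)))
  ok <- !is.na(indicator)
  d <- data.frame(time = dataset$time[ok], event = dataset$event[ok],
                  group = factor(ifelse(indicator[ok] == 1, "high", "low"),
                                 levels = c("low", "high")))
  if (any(table(d$group) == 0))
    stop("both split groups must be nonempty", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  if (sum(d$event) == 0) {
    p <- 1  # no events: the curves carry no discriminating information
  } else {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  }
  s <- summary(fit, censored = TRUE)
  tab <- data.frame(group = sub("^group=", "", as.character(s$strata)),
                    time = s$time, n_risk = s$n.risk, n_event = s$n.event,
                    surv = s$surv, stringsAsFactors = FALSE)
  structure(list(fit = fit, logrank_p = p, table = tab), class = "km_split")
}

#' @export
print.km_split <- function(x, ...) {
  cat(sprintf("km_split: log-rank p = %.4g\n", x$logrank_p))
  invisible(x)
}

#' Plot a Kaplan-Meier split
#' @param x a `km_split`.
#' @param ... passed to [survival::plot.survfit()].
#' @export
plot.km_split <- function(x, ...) {
  graphics::plot(x$fit, col = c("blue", "darkgreen"), xlab = "days",
                 ylab = "progression-free fraction", ...)
  graphics::legend("bottomleft", legend = c("low", "high"),
                   col = c("blue", "darkgreen"), lty = 1, bty = "n")
  invisible(x)
}

#' Kruskal-Wallis comparison of a metric across subgroups
#'
#' Rank-based H test (tie-corrected, chi-square reference) of whether a
#' metric differs across outcome subgroups.
#'
#' @param values numeric metric values.
#' @param labels subgroup labels, same length; at least two nonempty groups.
#' @return list with `statistic` (H), `df`, and `p`.
#' @export
kruskal_wallis_groups <- function(values, labels) {
  ok <- !is.na(values) & !is.na(labels)
  labels <- factor(labels[ok])
  if (nlevels(droplevels(labels)) < 2)
    stop("need at least two nonempty groups", call. = FALSE)
  kt <- stats::kruskal.test(values[ok], labels)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}
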