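test_that("endpoint derivation applies the cause-specific censoring rule", {
  # FFLP: distant failure first is a censoring cause
  r1 <- cohort_row(lp = 200, dp = 150, fu = 400)
  d1 <- derive_endpoint(r1, "FFLP")
  expect_equal(d1$time, 150)
  expect_equal(d1$event, 0L)
  # FFDP: distant failure before death is the event
  r2 <- cohort_row(dp = 300, death = 400, fu = 400)
  d2 <- derive_endpoint(r2, "FFDP")
  expect_equal(d2$time, 300)
  expect_equal(d2$event, 1L)
  # FFLRDP: no events -> censored at follow-up
  d3 <- derive_endpoint(cohort_row(fu = 900), "FFLRDP")
  expect_equal(d3$time, 900)
  expect_equal(d3$event, 0L)
  # simultaneous targeted and non-targeted failure counts as event
  d4 <- derive_endpoint(cohort_row(lp = 250, dp = 250, fu = 600), "FFLP")
  expect_equal(d4$event, 1L)
})

test_that("every record is either derived or logged as skipped", {
  recs <- rbind(cohort_row("A", lp = 100, fu = 500),
                cohort_row("B", fu = NA),
                cohort_row("C", dp = 300, fu = 300))
  expect_warning(d <- derive_endpoint(recs, "FFLP"), "skipped")
  expect_equal(nrow(d) + length(attr(d, "skipped")), nrow(recs))
  expect_equal(attr(d, "skipped"), "B")
})

test_that("derivation matches the brute-force rule evaluator on a grid", {
  days <- c(NA, 100, 200)
  grid <- expand.grid(lp = days, rp = days, dp = days, death = days)
  cases <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    cohort_row(sprintf("C%03d", i), lp = grid$lp[i], rp = grid$rp[i],
               dp = grid$dp[i], death = grid$death[i], fu = 400)))
  for (ep in c("FFLP", "FFLRP", "FFDP", "FFLRDP")) {
    got <- derive_endpoint(cases, ep)
    for (i in seq_len(nrow(cases))) {
      want <- endpoint_oracle(cases[i, ], ep)
      row <- got[got$id == cases$id[i], ]
      expect_equal(nrow(row), 1L)
      expect_equal(row$time, want$time)
      expect_equal(row$event, want$event)
    }
  }
})

test_that("boosted NED patients leave local endpoints but stay for FFDP", {
  recs <- rbind(cohort_row("ned80", arm = "80Gy"),
                cohort_row("lf80", arm = "80Gy", lp = 200),
                cohort_row("ned70", arm = "70Gy"),
                cohort_row("df80", arm = "80Gy", dp = 300))
  for (ep in c("FFLP", "FFLRP", "FFLRDP")) {
    kept <- apply_boost_exclusion(recs, ep)
    expect_setequal(kept$id, c("lf80", "ned70", "df80"))
    expect_equal(attr(kept, "n_excluded"), 1L)
  }
  expect_setequal(apply_boost_exclusion(recs, "FFDP")$id, recs$id)
})

test_that("median dichotomization uses a strict cut with ties to low", {
  expect_equal(as.vector(dichotomize_at_median(c(1, 2, 3))), c(0L, 0L, 1L))
  expect_equal(as.vector(dichotomize_at_median(c(5, 5, 5, 5))), rep(0L, 4))
  # even length: midpoint of the central order statistics
  v <- c(4, 1, 3, 2)
  ind <- dichotomize_at_median(v)
  expect_equal(attr(ind, "cutpoint"), 2.5)
  expect_equal(as.vector(ind), as.integer(v > 2.5))
  expect_error(dichotomize_at_median(c(NA, 1)), "non-missing")
})

test_that("cox interaction contrasts are coefficient transforms of the fit", {
  sp <- cohort_spec(n_lahnscc = 100, n_opscc = 100,
                    log_hr_metric_lahnscc = log(3), log_hr_p16 = 0,
                    event_type_probs = c(lp = 0, rp = 0, dp = 1),
                    p_simultaneous = 0, seed = 77)
  d <- derive_endpoint(generate_cohort(sp)$cohort, "FFDP")
  res <- fit_cox_interaction(d, metric = "indicator")
  expect_s3_class(res, "cox_result")
  fit <- attr(res, "fit")
  beta <- coef(fit)
  expect_equal(res$hr[res$contrast == "metric_LAHNSCC"],
               unname(exp(beta["x_lahn"])))
  expect_equal(res$hr[res$contrast == "difference_in_effects"],
               unname(exp(beta["x_op"] - beta["x_lahn"])))
  expect_true(all(res$ci_low < res$hr & res$hr < res$ci_high))
  expect_true(all(res$hr > 0))
})

test_that("null and alternative cox simulations behave as planted", {
  # null metric: both within-group CIs cover 1
  sp0 <- cohort_spec(n_lahnscc = 100, n_opscc = 100, log_hr_p16 = 0,
                     log_hr_metric_lahnscc = 0, log_hr_metric_opscc = 0,
                     event_type_probs = c(lp = 0, rp = 0, dp = 1),
                     p_simultaneous = 0, seed = 42)
  d0 <- derive_endpoint(generate_cohort(sp0)$cohort, "FFDP")
  r0 <- fit_cox_interaction(d0, metric = "indicator")
  within <- r0[r0$contrast %in% c("metric_LAHNSCC", "metric_p16+OPSCC"), ]
  expect_true(all(within$ci_low < 1 & 1 < within$ci_high))
  diffrow <- r0[r0$contrast == "difference_in_effects", ]
  expect_true(diffrow$ci_low < 1 && 1 < diffrow$ci_high)

  # planted within-LAHNSCC effect is recovered inside its CI
  sp1 <- cohort_spec(n_lahnscc = 200, n_opscc = 200,
                     log_hr_metric_lahnscc = log(4), log_hr_p16 = 0,
                     event_type_probs = c(lp = 0, rp = 0, dp = 1),
                     p_simultaneous = 0, seed = 43)
  d1 <- derive_endpoint(generate_cohort(sp1)$cohort, "FFDP")
  r1 <- fit_cox_interaction(d1, metric = "indicator")
  lahn <- r1[r1$contrast == "metric_LAHNSCC", ]
  expect_true(lahn$ci_low < 4 && 4 < lahn$ci_high)
})

test_that("a stratum without events flags the model", {
  d <- data.frame(time = c(100, 200, 300, 400, 150, 250),
                  event = c(1, 1, 0, 0, 0, 0),
                  p16 = c(0, 0, 0, 1, 1, 1),
                  metric = c(1, 0, 1, 0, 1, 0))
  res <- suppressWarnings(fit_cox_interaction(d, metric = "metric"))
  expect_true(attr(res, "flagged"))
  expect_gt(length(attr(res, "diagnostics")), 0)
})

test_that("BH adjustment matches the step-up oracle and validates input", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  set.seed(51)
  for (r in 1:20) {
    p <- round(runif(sample(1:8, 1)), 3)
    expect_equal(fdr_adjust(p), bh_brute(p))
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # grouping adjusts within families only
  p <- c(0.01, 0.02, 0.01, 0.02)
  fam <- c("a", "a", "b", "b")
  expect_equal(fdr_adjust(p, fam), c(bh_brute(p[1:2]), bh_brute(p[3:4])))
})

test_that("kaplan-meier estimates equal the hand-computed product limit", {
  d <- data.frame(time = c(2, 4, 4, 6, 8), event = c(1, 1, 0, 1, 0))
  km <- km_by_split(rbind(d, d), rep(c(0, 1), each = 5))
  # S(2) = 4/5, S(4) = 4/5 * 3/4, S(6) = 0.6 * 1/2
  for (g in c("low", "high")) {
    tab <- km$table[km$table$group == g & km$table$n_event > 0, ]
    expect_equal(tab$surv, c(0.8, 0.6, 0.3))
  }
  # identical curves -> log-rank cannot distinguish them
  expect_gt(km$logrank_p, 0.99)
  # no events -> curves constant at 1
  d0 <- data.frame(time = c(5, 6, 7, 8), event = 0)
  km0 <- km_by_split(d0, c(0, 0, 1, 1))
  expect_true(all(km0$table$surv == 1))
  expect_error(km_by_split(d0, c(0, 0, 0, 0)), "nonempty")
})

test_that("KM curves are non-increasing step functions from 1", {
  sp <- cohort_spec(n_lahnscc = 60, n_opscc = 60, seed = 4)
  d <- suppressWarnings(derive_endpoint(generate_cohort(sp)$cohort, "FFLRDP"))
  km <- km_by_split(d, dichotomize_at_median(d$metric))
  for (g in c("low", "high")) {
    s <- km$table$surv[km$table$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_lte(max(s), 1)
  }
})

test_that("kruskal-wallis agrees with rank arithmetic, with and without ties", {
  out <- kruskal_wallis_groups(c(1, 2, 3, 101, 102, 103),
                               rep(c("a", "b"), each = 3))
  expect_equal(out$statistic, 27 / 7, tolerance = 1e-12)  # 12/42*87 - 21
  expect_equal(out$df, 1)

  set.seed(52)
  v <- sample(1:5, 30, replace = TRUE)  # heavy ties
  g <- rep(c("a", "b", "c"), 10)
  out2 <- kruskal_wallis_groups(v, g)
  expect_equal(out2$statistic, kw_brute(v, g), tolerance = 1e-10)
  expect_error(kruskal_wallis_groups(1:5, rep("a", 5)), "two nonempty")
})
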