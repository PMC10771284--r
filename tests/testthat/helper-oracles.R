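# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementation.

# Benjamini-Hochberg step-up, literal definition: sort ascending, compute
# p_(i) * m / i, enforce monotonicity from the largest rank down, cap at 1.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, ps[i] * m / i)
    adj[i] <- min(running, 1)
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Censoring-rule evaluator: per-record if/else walk over the event calendar.
endpoint_oracle <- function(row, endpoint) {
  targeted <- switch(endpoint,
                     FFLP = c("lp_day"),
                     FFLRP = c("lp_day", "rp_day"),
                     FFDP = c("dp_day"),
                     FFLRDP = c("lp_day", "rp_day", "dp_day"))
  censoring <- c(setdiff(c("lp_day", "rp_day", "dp_day"), targeted),
                 "death_day", "last_fu_day")
  t_ev <- Inf
  for (col in targeted) {
    v <- row[[col]]
    if (!is.na(v) && v < t_ev) t_ev <- v
  }
  t_cn <- Inf
  for (col in censoring) {
    v <- row[[col]]
    if (!is.na(v) && v < t_cn) t_cn <- v
  }
  if (!is.finite(t_ev) && !is.finite(t_cn)) return(NULL)
  if (is.finite(t_ev) && t_ev <= t_cn) {
    list(time = t_ev, event = 1L)
  } else if (is.finite(t_cn)) {
    list(time = t_cn, event = 0L)
  } else {
    NULL
  }
}

# Tie-corrected Kruskal-Wallis H from first principles.
kw_brute <- function(values, labels) {
  r <- rank(values)
  N <- length(values)
  h <- 0
  for (g in unique(labels)) {
    rg <- r[labels == g]
    h <- h + sum(rg)^2 / length(rg)
  }
  h <- 12 / (N * (N + 1)) * h - 3 * (N + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h / correction
}
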