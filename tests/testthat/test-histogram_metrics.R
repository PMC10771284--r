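test_that("mean ADC and its summation oracle agree", {
  expect_equal(mean_adc(make_adc(rep(1.5, 4)), make_mask(c(4, 1, 1))), 1.5)
  expect_equal(mean_adc(make_adc(c(1, 2)), make_mask(c(2, 1, 1))), 1.5)
  set.seed(3)
  v <- draw_mixture(1e4, 1.0, 1.8, 0.15, 0.2)
  a <- make_adc(v)
  m <- make_mask(c(1e4, 1, 1))
  s <- 0
  for (x in v) s <- s + x
  expect_equal(mean_adc(a, m), s / length(v), tolerance = 1e-12)
  expect_error(mean_adc(a, make_mask(c(1e4, 1, 1), where = FALSE)),
               "no valid voxels")
})

test_that("low-ADC subvolume applies strict threshold and voxel volume", {
  sp <- c(1.2, 1.2, 4.8)
  a <- make_adc(rep(2.0, 10), spacing = sp)
  m <- make_mask(c(10, 1, 1), spacing = sp)
  expect_equal(low_adc_subvolume(a, m), 0)

  a2 <- make_adc(c(rep(0.9, 1000), rep(2, 24)), spacing = sp)
  m2 <- make_mask(c(1024, 1, 1), spacing = sp)
  expect_equal(low_adc_subvolume(a2, m2), 1000 * 6.912 / 1000)  # 6.912 cm^3

  a3 <- make_adc(c(1.2, 1.19999), spacing = sp)
  m3 <- make_mask(c(2, 1, 1), spacing = sp)
  expect_equal(low_adc_subvolume(a3, m3), 1 * 6.912 / 1000)  # 1.2 not counted
})

test_that("tv_ladc never exceeds gtv volume; equality iff all voxels low", {
  set.seed(5)
  for (r in 1:10) {
    v <- runif(200, 0, 2.69)
    a <- make_adc(v)
    m <- make_mask(c(200, 1, 1))
    tv <- low_adc_subvolume(a, m)
    expect_lte(tv, mask_volume(m))
    if (all(v < 1.2)) expect_equal(tv, mask_volume(m))
  }
})

test_that("histogram uses left-closed right-open bins of width 0.1", {
  h <- hist_from_values(0.05)
  expect_equal(h$counts[1], 1L)
  expect_equal(sum(h$counts), 1L)
  h2 <- hist_from_values(0.1)  # exactly on an edge -> next bin
  expect_equal(h2$counts[1], 0L)
  expect_equal(h2$counts[2], 1L)
  expect_equal(length(h2$counts), 27L)
  expect_equal(h2$bin_edges, seq(0, 2.7, by = 0.1))
})

test_that("bin counts equal a brute-force per-voxel assignment", {
  set.seed(9)
  v <- draw_mixture(1e4, 1.0, 1.8, 0.15, 0.2)
  h <- hist_from_values(v)
  brute <- integer(27)
  for (x in v) {
    b <- 1L
    while (x >= b * 0.1) b <- b + 1L  # first bin whose right edge exceeds x
    brute[b] <- brute[b] + 1L
  }
  expect_equal(h$counts, brute)
  expect_equal(sum(h$counts), h$total)
  # out-of-support values must have been excluded upstream
  expect_error(hist_from_values(c(1, 2.7)), "exclude_necrosis")
})

test_that("bimodal fit recovers planted mixture parameters", {
  set.seed(21)
  v <- draw_mixture(1e5, 1.0, 1.8, 0.15, 0.2)
  f <- fit_bimodal(hist_from_values(v), seed = 1)
  expect_false(f$unimodal)
  expect_lt(abs(f$L$mu - 1.0), 0.02)
  expect_lt(abs(f$H$mu - 1.8), 0.02)
  expect_true(f$L$mu <= f$H$mu)
  expect_gt(f$L$sigma, 0)
  expect_gt(f$H$sigma, 0)
})

test_that("mirrored mixtures give mirrored component means", {
  set.seed(22)
  mid <- 1.35
  v <- draw_mixture(5e4, 1.0, 1.7, 0.12, 0.12)
  vm <- 2 * mid - v  # reflection about the midpoint
  f <- fit_bimodal(hist_from_values(v), seed = 1)
  fm <- fit_bimodal(hist_from_values(vm), seed = 1)
  expect_lt(abs((2 * mid - fm$H$mu) - f$L$mu), 0.03)
  expect_lt(abs((2 * mid - fm$L$mu) - f$H$mu), 0.03)
})

test_that("single-Gaussian histograms trigger the 50/50 unimodal rule", {
  set.seed(23)
  v <- draw_trunc(2e4, 1.4, 0.2)
  f <- fit_bimodal(hist_from_values(v), seed = 1)
  expect_true(f$unimodal)
  expect_identical(f$L$mu, f$H$mu)
  expect_identical(f$L$sigma, f$H$sigma)
  expect_equal(f$L$A, f$H$A)  # amplitude split 50/50
  expect_lt(abs(f$L$mu - 1.4), 0.02)
})

test_that("unimodality rule fires on near peaks or negligible amplitude", {
  two_far <- structure(list(L = list(mu = 1.0, sigma = 0.15, A = 100),
                            H = list(mu = 1.8, sigma = 0.2, A = 100)),
                       class = "bimodal_fit")
  expect_false(detect_unimodality(two_far))
  near <- two_far
  near$H$mu <- 1.05  # 0.05 apart with sigma 0.2
  expect_true(detect_unimodality(near))
  tiny <- two_far
  tiny$H$A <- 2  # 2% of the major amplitude
  expect_true(detect_unimodality(tiny))
})

test_that("an adequate single-Gaussian fit overrides a spurious split", {
  set.seed(28)
  v <- draw_trunc(1e4, 1.2, 0.18)
  h <- hist_from_values(v)
  # even a fit object with well-separated components is overruled when one
  # Gaussian already explains the counts to within sampling noise
  spurious <- structure(list(L = list(mu = 0.9, sigma = 0.1, A = 300),
                             H = list(mu = 1.25, sigma = 0.18, A = 2000)),
                        class = "bimodal_fit")
  expect_true(detect_unimodality(spurious, h))
  # a genuinely bimodal histogram is not overruled
  vb <- draw_mixture(1e4, 1.0, 1.8, 0.15, 0.2)
  hb <- hist_from_values(vb)
  sep_fit <- fit_bimodal(hb, seed = 1)
  expect_false(detect_unimodality(sep_fit, hb))
})

test_that("two-component residual never exceeds the single-Gaussian one", {
  set.seed(24)
  for (r in 1:5) {
    v <- draw_mixture(2e4, runif(1, 0.9, 1.1), runif(1, 1.6, 1.9),
                      0.15, 0.2, w_l = runif(1, 0.3, 0.7))
    h <- hist_from_values(v)
    f <- fit_bimodal(h, seed = r)
    single <- adcboost:::fit_single_gaussian(h)
    expect_lte(f$residual, single$residual * (1 + 1e-9))
  }
})

test_that("the fit is deterministic given (hist, restarts, seed)", {
  set.seed(25)
  v <- draw_mixture(2e4, 1.0, 1.75, 0.15, 0.2)
  h <- hist_from_values(v)
  f1 <- fit_bimodal(h, restarts = 8, seed = 99)
  f2 <- fit_bimodal(h, restarts = 8, seed = 99)
  expect_identical(f1, f2)
  expect_error(fit_bimodal(hist_from_values(runif(10, 0.5, 2.5))),
               "minimum")
})

test_that("pooled nodal metrics equal union-volume brute force", {
  sp <- c(1.2, 1.2, 4.8)
  set.seed(26)
  shape <- c(40, 40, 6)
  vals <- array(draw_mixture(prod(shape), 1.0, 1.8, 0.15, 0.2), shape)
  a <- make_adc(vals, spacing = sp)
  m1 <- make_mask(shape, sp); m1$mask[] <- FALSE; m1$mask[1:20, 1:20, ] <- TRUE
  m2 <- make_mask(shape, sp); m2$mask[] <- FALSE; m2$mask[15:30, 15:30, ] <- TRUE
  m1$label <- "nodal-1"; m2$label <- "nodal-2"

  tm <- total_nodal_metrics(a, list(m1, m2), seed = 1)
  union_count <- 0
  for (i in 1:40) for (j in 1:40) for (k in 1:6)
    if (m1$mask[i, j, k] || m2$mask[i, j, k]) union_count <- union_count + 1
  expect_equal(tm$gtv_volume, union_count * prod(sp) / 1000)
  expect_equal(tm$label, "nodal-total")

  # disjoint masks: volumes add
  m3 <- make_mask(shape, sp); m3$mask[] <- FALSE; m3$mask[31:40, 31:40, ] <- TRUE
  m3$label <- "nodal-3"
  tm2 <- total_nodal_metrics(a, list(m1, m3), seed = 1)
  expect_equal(tm2$gtv_volume, mask_volume(m1) + mask_volume(m3))

  # single mask: identical to per-tumor metrics
  tm3 <- total_nodal_metrics(a, list(m1), seed = 1)
  per <- tumor_metrics(a, m1, seed = 1)
  expect_equal(tm3$mean_adc, per$mean_adc)
  expect_equal(tm3$tv_ladc, per$tv_ladc)
  expect_error(total_nodal_metrics(a, list()), "no nodal masks")
})

test_that("group-averaged histograms are normalize-then-mean, unit area", {
  set.seed(27)
  hs <- lapply(1:4, function(i)
    hist_from_values(draw_mixture(5000 * i, 1.0, 1.8, 0.15, 0.2)))
  avg <- group_average_histogram(hs)
  w <- 0.1
  # brute-force oracle
  mat <- sapply(hs, function(h) h$counts / sum(h$counts) / w)
  expect_equal(avg$density, apply(mat, 1, function(r) sum(r) / length(r)),
               tolerance = 1e-12)
  expect_equal(sum(avg$density) * w, 1, tolerance = 1e-12)
  # identical histograms average to themselves
  same <- group_average_histogram(list(hs[[1]], hs[[1]]))
  expect_equal(same$density, hs[[1]]$counts / hs[[1]]$total / w)
  # mixed bin schemes rejected
  bad <- hs[[1]]; bad$bin_edges <- bad$bin_edges + 0.05
  expect_error(group_average_histogram(list(hs[[1]], bad)), "bin schemes")
})
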