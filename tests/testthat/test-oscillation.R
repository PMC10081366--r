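tone_series <- function(period_min, n = 120, amplitude = 5, baseline = 60) {
  t <- 0:(n - 1)
  fscav_series(t, baseline + amplitude * sin(2 * pi * t / period_min))
}

test_that("bandpass rejects DC and preserves the oscillation band", {
  flat <- fscav_series(0:119, rep(60, 120))
  out <- bandpass(flat)
  expect_lt(max(abs(out$concentration_nM)), 1e-6 * 60)
  # 8-minute tone (0.00208 Hz) sits in the passband
  tone <- tone_series(8)
  bp <- bandpass(tone)
  core <- 20:100  # avoid filter edge transients
  ratio <- stats::sd(bp$concentration_nM[core]) /
    stats::sd(tone$concentration_nM[core] - 60)
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})

test_that("bandpass attenuates fast out-of-band components", {
  # fastest representable oscillation at 1-min sampling: 2-min period
  # (0.0083 Hz), well above the 0.005 Hz edge
  n <- 240
  fast <- fscav_series(0:(n - 1), 60 + 5 * cos(pi * (0:(n - 1))))
  bp <- bandpass(fast)
  core <- 30:(n - 30)
  expect_lt(stats::sd(bp$concentration_nM[core]) / 5, 0.05)
})

test_that("short series warn on bandpass", {
  expect_warning(bandpass(fscav_series(0:29, rnorm(30, 60))),
                 class = "serovolt_short_series_warning")
})

test_that("autocorrelation is 1 at lag zero and bounded", {
  s <- simulate_basal_series(basal_spec(oscillation_period_min = 8), seed = 3)
  ac <- autocorrelation(s, 40)
  expect_identical(ac$r[1], 1)
  expect_true(all(abs(ac$r) <= 1 + 1e-12))
  # long pure sinusoid: correlation recurs at one full period
  tone <- tone_series(8, n = 400)
  ac8 <- autocorrelation(tone, 10)
  expect_gt(ac8$r[9], 0.95)
  # white noise decorrelates at the sampling bound
  wn <- fscav_series(0:499, withr::with_seed(9, rnorm(500)))
  acw <- autocorrelation(wn, 10)
  expect_true(all(abs(acw$r[-1]) < 3 / sqrt(500)))
  expect_error(autocorrelation(fscav_series(0:9, rep(1, 10)), 5),
               class = "serovolt_undefined_correlation_error")
  expect_error(autocorrelation(wn, 500), class = "serovolt_validation_error")
})

test_that("sliding-window correlation matches lag structure and shape", {
  tone <- tone_series(8, n = 120)
  m <- sliding_window_correlation(tone, window_min = 25, lags = 0:10)
  expect_equal(dim(m), c(120 - 25 - 10 + 1, 11))
  expect_true(all(m >= -1 - 1e-12 & m <= 1 + 1e-12, na.rm = TRUE))
  # lag 8 = one full period: all columns near 1; lag 4 = anti-phase: near -1
  expect_true(all(m[, "8"] > 0.95))
  expect_true(all(m[, "4"] < -0.95))
  expect_true(all(abs(m[, "0"] - 1) < 1e-12))
  # zero-variance windows yield NA entries, not errors
  x <- c(rep(1, 30), rnorm(30))
  m2 <- sliding_window_correlation(fscav_series(0:59, x), 25, lags = 0:2)
  expect_true(any(is.na(m2)))
  expect_error(sliding_window_correlation(tone, 200, lags = 0:10),
               class = "serovolt_validation_error")
})

test_that("Welch PSD localises tones and is flat for white noise", {
  tone <- tone_series(8, n = 240)
  psd <- welch_psd(tone)
  bin <- diff(psd$frequency_hz[1:2])
  expect_lt(abs(psd$frequency_hz[which.max(psd$power)] - 1 / 480), bin)
  expect_equal(sum(psd$normalized_power), 1, tolerance = 1e-9)
  expect_true(all(diff(psd$frequency_hz) > 0))
  # averaged white-noise spectra stay within a factor-5 spread
  flatness <- purrr::map(1:6, function(i) {
    wn <- withr::with_seed(100 + i, rnorm(600))
    welch_psd(fscav_series(0:599, wn), segment_length = 100)$power
  })
  avg <- purrr::reduce(flatness, `+`) / 6
  expect_lt(max(avg) / min(avg), 5)
  expect_error(welch_psd(fscav_series(0:5, rnorm(6)), segment_length = 6),
               class = "serovolt_validation_error")
})

test_that("in-band tones concentrate bandpassed power near the tone", {
  s <- simulate_basal_series(
    basal_spec(oscillation_period_min = 8, noise_sd_nM = 0), seed = 1)
  psd <- welch_psd(bandpass(s))
  i0 <- which.max(psd$power)
  near <- psd$normalized_power[max(1, i0 - 2):min(nrow(psd), i0 + 2)]
  expect_gt(sum(near), 0.8)
})

test_that("weighted frequency is the spectral centre of mass", {
  psd <- welch_psd(tone_series(8, n = 240))
  wf <- weighted_frequency(psd)
  expect_gte(wf, min(psd$frequency_hz))
  expect_lte(wf, max(psd$frequency_hz))
  bin <- diff(psd$frequency_hz[1:2])
  expect_lt(abs(wf - 1 / 480), 2 * bin)
  # symmetry: equal mass at two frequencies averages them
  two <- serovolt:::psd_result(c(0.001, 0.003), c(1, 1))
  expect_equal(weighted_frequency(two), 0.002)
  expect_equal(weighted_frequency(two, normalize = FALSE), 0.004)
  # shifting mass upward raises the WF
  lo <- serovolt:::psd_result(c(0.001, 0.003), c(2, 1))
  hi <- serovolt:::psd_result(c(0.001, 0.003), c(1, 2))
  expect_gt(weighted_frequency(hi), weighted_frequency(lo))
  zero <- serovolt:::psd_result(c(0.001, 0.003), c(0, 0))
  expect_error(weighted_frequency(zero), class = "serovolt_undefined_error")
})

test_that("pre/post comparison recovers the direction of a period shift", {
  make_cohort <- function(period, seeds) {
    purrr::map(seeds, function(sd) simulate_basal_series(
      basal_spec(oscillation_period_min = period, noise_sd_nM = 1), seed = sd))
  }
  pre <- make_cohort(10, 1:5)
  post <- make_cohort(6, 11:15)
  cmp <- compare_pre_post(pre, post)
  expect_true(all(cmp$delta > 0))
  expect_equal(attr(cmp, "direction"), "uptake1-like")
  rev_cmp <- compare_pre_post(post, pre)
  expect_true(all(rev_cmp$delta < 0))
  expect_equal(attr(rev_cmp, "direction"), "uptake2-like")
  same <- compare_pre_post(pre, pre)
  expect_true(all(same$delta == 0))
  expect_error(compare_pre_post(pre, post[1:3]),
               class = "serovolt_pairing_error")
})
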