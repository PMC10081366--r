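test_that("the 2D filter passes DC unchanged and needs two sweeps", {
  vs <- voltammogram_set(matrix(5, 40, 64))
  out <- filter_color_plot(vs)
  expect_equal(out$current, matrix(5, 40, 64), tolerance = 1e-9)
  expect_error(filter_color_plot(voltammogram_set(matrix(1, 1, 64))),
               class = "serovolt_validation_error")
})

test_that("slow-axis tones are shaped by the 3rd-order Butterworth response", {
  n_sweeps <- 400
  t <- (seq_len(n_sweeps) - 1) / 10  # 10 Hz sweep rate
  butter_gain <- function(f, fc, order = 3) 1 / sqrt(1 + (f / fc)^(2 * order))
  for (f0 in c(0.5, 4)) {
    tone <- matrix(sin(2 * pi * f0 * t), n_sweeps, 16)
    out <- filter_color_plot(voltammogram_set(tone))
    # use the central portion to dodge residual edge effects
    core <- 50:(n_sweeps - 50)
    gain <- stats::sd(out$current[core, 1]) / stats::sd(tone[core, 1])
    if (f0 < 2.5) {
      expect_gt(gain, 0.99)
    } else {
      expect_lt(gain, butter_gain(4, 2.5) * 1.05)
    }
  }
})

test_that("calibrated trace extraction scales a known current step", {
  n <- 60
  mat <- matrix(2, n, 32)            # constant 2 nA background
  mat[31:n, 10] <- 3                 # 1 nA step at the peak index
  vs <- voltammogram_set(mat, sweep_rate_hz = 10)
  tr <- extract_calibrated_trace(vs, peak_index = 10,
                                 calibration_factor = 49.5,
                                 factor_units = "uM_per_nA")
  expect_equal(tr$concentration_nM[1:30], rep(0, 30), tolerance = 1e-12)
  expect_equal(tr$concentration_nM[31:n], rep(49.5, 30), tolerance = 1e-9)
  # an all-background plot gives a zero trace; a zero factor too
  expect_true(all(extract_calibrated_trace(
    voltammogram_set(matrix(2, 20, 32)), 10, 49.5)$concentration_nM == 0))
  expect_true(all(extract_calibrated_trace(vs, 10, 0)$concentration_nM == 0))
  expect_error(extract_calibrated_trace(voltammogram_set(matrix(1, 5, 32)),
                                        10, 49.5),
               class = "serovolt_validation_error")
})

make_peaked_trace <- function(peaks, baseline = 10, duration = 40,
                              stim_start = 10) {
  t <- seq(0, duration, 0.1)
  y <- rep(baseline, length(t))
  for (pk in peaks) {
    y <- y + pk$height * exp(-(t - pk$at)^2 / (2 * 0.5^2))
  }
  concentration_trace(t, y, stim_start, stim_start + 2)
}

test_that("amplitude detection finds the tallest qualifying local maximum", {
  tr <- make_peaked_trace(list(list(height = 80, at = 12)))
  amp <- detect_amp_max(tr)
  expect_true(amp$found)
  expect_equal(amp$amp_max, 80, tolerance = 1e-3)
  expect_equal(amp$t_peak, 12, tolerance = 0.1)
  # two maxima: the taller one wins
  tr2 <- make_peaked_trace(list(list(height = 60, at = 18),
                                list(height = 80, at = 12)))
  expect_equal(detect_amp_max(tr2)$amp_max, 80, tolerance = 1e-3)
  # flat trace: not-found result, not an error
  flat <- concentration_trace(seq(0, 40, 0.1), rep(10, 401), 10, 12)
  expect_false(detect_amp_max(flat)$found)
  # invariant to adding a constant
  tr3 <- tr
  tr3$concentration_nM <- tr3$concentration_nM + 123
  expect_equal(detect_amp_max(tr3)$amp_max, amp$amp_max, tolerance = 1e-9)
})

test_that("amplitude detection requires a baseline segment", {
  short <- concentration_trace(seq(0, 10, 0.1), rep(0, 101), 2, 4)
  expect_error(detect_amp_max(short), class = "serovolt_validation_error")
})

test_that("exponential decay fits return t_half = ln(2)/k", {
  t <- seq(0, 30, 0.1)
  for (k_true in c(log(2), 0.1, 0.5)) {
    y <- 50 * exp(-k_true * pmax(t - 5, 0)) + 3
    tr <- concentration_trace(t, y, 1, 3)
    fit <- fit_half_life(tr, 5)
    expect_equal(fit$k, k_true, tolerance = 1e-4)
    expect_equal(fit$t_half, log(2) / fit$k)  # identity, exact
    expect_false(fit$degenerate)
  }
  # k = 0.1 prints the textbook half-life
  y <- 50 * exp(-0.1 * pmax(t - 5, 0))
  expect_equal(fit_half_life(concentration_trace(t, y, 1, 3), 5)$t_half,
               6.931, tolerance = 1e-3)
})

test_that("decay rate survives 1% noise and flags non-decaying segments", {
  t <- seq(0, 30, 0.1)
  y <- 50 * exp(-0.3 * pmax(t - 5, 0)) + 3
  noisy <- y + withr::with_seed(21, stats::rnorm(length(t), 0, 0.5))
  fit <- fit_half_life(concentration_trace(t, noisy, 1, 3), 5)
  expect_lt(abs(fit$k / 0.3 - 1), 0.05)
  rising <- concentration_trace(t, 10 + t, 1, 3)
  expect_true(fit_half_life(rising, 5)$degenerate)
})

test_that("inhibition amplitude reads the windowed dip below baseline", {
  t <- seq(0, 40, 0.1)
  base <- rep(30, length(t))
  flat <- concentration_trace(t, base, 10, 12)
  expect_equal(detect_inhibition(flat), 0)
  dip <- base - 12 * exp(-(t - 15)^2 / (2 * 0.8^2))
  expect_equal(detect_inhibition(concentration_trace(t, dip, 10, 12)), 12,
               tolerance = 1e-3)
  late <- base - 12 * exp(-(t - 35)^2 / (2 * 0.8^2))
  expect_equal(detect_inhibition(concentration_trace(t, late, 10, 12)), 0,
               tolerance = 1e-6)
})

test_that("filtering commutes with extraction on constant plots", {
  vs <- voltammogram_set(matrix(4, 30, 32))
  a <- extract_calibrated_trace(filter_color_plot(vs), 10, 49.5)
  b <- extract_calibrated_trace(vs, 10, 49.5)
  expect_equal(a$concentration_nM, b$concentration_nM, tolerance = 1e-9)
})
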