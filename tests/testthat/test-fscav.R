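test_that("background subtraction removes the mean of the first ten sweeps", {
  mat <- matrix(rep(sin(seq_len(50) / 5), each = 20), 20, 50)
  vs <- voltammogram_set(mat)
  out <- background_subtract(vs)
  expect_equal(out$current, matrix(0, 20, 50), tolerance = 1e-12)
  # a perturbation on one sweep survives alone
  mat2 <- mat
  mat2[15, 25] <- mat2[15, 25] + 7
  out2 <- background_subtract(voltammogram_set(mat2))
  expect_equal(out2$current[15, 25], 7, tolerance = 1e-12)
  out2$current[15, 25] <- 0
  expect_equal(out2$current, matrix(0, 20, 50), tolerance = 1e-12)
  # idempotent once the first ten sweeps are zero
  expect_equal(background_subtract(out)$current, out$current,
               tolerance = 1e-12)
  expect_error(background_subtract(voltammogram_set(matrix(1, 10, 50))),
               class = "serovolt_validation_error")
})

test_that("the third post-adsorption CV is selected", {
  mat <- matrix(0, 25, 40)
  mat[23, 7] <- 99  # boundary 21 -> third post-adsorption sweep is row 23
  vs <- voltammogram_set(mat, metadata = list(adsorption_boundary = 21L))
  cv <- select_measurement_cv(vs)
  expect_equal(cv[7], 99)
  vs$metadata$adsorption_boundary <- 24L
  expect_error(select_measurement_cv(vs), class = "serovolt_validation_error")
  vs$metadata$adsorption_boundary <- NULL
  expect_error(select_measurement_cv(vs), class = "serovolt_metadata_error")
})

test_that("Simpson integration is exact on a parabolic peak", {
  # inverted parabola y = h (1 - (x/w)^2) on [-w, w]: area = 4 h w / 3;
  # Simpson is exact on quadratics, so the match is to machine precision
  fs <- 1e5
  w <- 150
  x <- seq(-w, w)
  y <- 5 * (1 - (x / w)^2)
  q <- suppressWarnings(integrate_peak(y, c(1, length(y)), sample_rate_hz = fs))
  analytic <- 4 * 5 * (w / fs) / 3 * 1e3
  expect_equal(q, analytic, tolerance = 1e-12)
  expect_equal(suppressWarnings(
    integrate_peak(rep(0, 100), c(1, 100), sample_rate_hz = fs)), 0)
})

test_that("a Gaussian on a sloped baseline is recovered within 2%", {
  fs <- 5e5
  x <- seq_len(1000)
  area_nAs <- 0.02
  sigma <- 15
  peak <- area_nAs * fs / (sigma * sqrt(2 * pi)) *
    exp(-(x - 500)^2 / (2 * sigma^2))
  ramp <- 0.5 + 0.002 * x
  # a monotone ramp leaves no left minimum: the documented edge fallback fires
  expect_warning(q <- integrate_peak(peak + ramp, c(350, 650),
                                     sample_rate_hz = fs),
                 class = "serovolt_bounds_warning")
  expect_lt(abs(q / (area_nAs * 1e3) - 1), 0.02)
})

test_that("flanking local minima set the integration bounds", {
  fs <- 5e5
  x <- seq_len(401)
  area_nAs <- 0.02
  sig <- 15
  main <- area_nAs * fs / (sig * sqrt(2 * pi)) *
    exp(-(x - 200)^2 / (2 * sig^2))
  # shallow valleys at +/- 4 sigma give strict minima on both flanks
  dips <- exp(-(x - 140)^2 / (2 * 8^2)) + exp(-(x - 260)^2 / (2 * 8^2))
  y <- main - dips + 2
  expect_no_warning(q <- integrate_peak(y, c(100, 300), sample_rate_hz = fs))
  expect_lt(abs(q / (area_nAs * 1e3) - 1), 0.02)
})

test_that("edge-bounded integration cancels any straight-line addition", {
  # a window inside +/- 1 sigma holds no local minimum, so both calls fall
  # back to the same window edges and the straight line cancels exactly
  fs <- 5e5
  x <- seq_len(401)
  y <- 3 * exp(-(x - 201)^2 / (2 * 20^2))
  q0 <- suppressWarnings(integrate_peak(y, c(180, 222), sample_rate_hz = fs))
  q1 <- suppressWarnings(integrate_peak(y + 5 - 0.03 * x, c(180, 222),
                                        sample_rate_hz = fs))
  expect_equal(q0, q1, tolerance = 1e-9)
})

test_that("calibration regression reproduces constructed lines", {
  std <- tibble::tibble(concentration_nM = c(10, 25, 50, 100),
                        charge_pC = 2 * c(10, 25, 50, 100) + 1)
  m <- suppressWarnings(fit_calibration(std))
  expect_equal(m$slope, 2, tolerance = 1e-9)
  expect_equal(m$intercept, 1, tolerance = 1e-9)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)
  expect_true(m$valid)
  two <- suppressWarnings(fit_calibration(
    tibble::tibble(concentration_nM = c(10, 50), charge_pC = c(3, 11))))
  expect_equal(two$slope, 0.2, tolerance = 1e-12)
  expect_equal(two$r_squared, 1, tolerance = 1e-9)
  neg <- suppressWarnings(fit_calibration(
    tibble::tibble(concentration_nM = c(10, 50), charge_pC = c(11, 3))))
  expect_false(neg$valid)
  expect_error(fit_calibration(
    tibble::tibble(concentration_nM = c(10, 10), charge_pC = c(1, 2))),
    class = "serovolt_rank_error")
})

test_that("synthesized files round-trip to their concentrations within 2%", {
  shape <- default_shape()
  window <- c(250, 400)
  std <- c(10, 25, 50, 100)
  charges <- purrr::map_dbl(std, function(cc) {
    v <- synthesize_fscav_file(cc, shape, seed = 100 + cc)
    suppressWarnings(integrate_peak(select_measurement_cv(background_subtract(v)),
                                    window, v$sample_rate_hz))
  })
  model <- suppressWarnings(fit_calibration(
    tibble::tibble(concentration_nM = std, charge_pC = charges)))
  truth <- c(18, 42, 77)
  vsets <- purrr::map(truth, ~ synthesize_fscav_file(.x, shape, seed = 500 + .x))
  ser <- suppressWarnings(process_series(vsets, model, window))
  expect_equal(nrow(ser), 3)
  expect_true(all(abs(ser$concentration_nM / truth - 1) < 0.02))
  expect_equal(ser$time_min, c(0, 1, 2))
})

test_that("series processing floors at zero and handles empty input", {
  shape <- default_shape()
  model <- suppressWarnings(fit_calibration(
    tibble::tibble(concentration_nM = c(10, 100),
                   charge_pC = c(10 * shape$calibration_slope + 5,
                                 100 * shape$calibration_slope + 5))))
  # a zero-concentration file integrates below the positive intercept
  vs <- synthesize_fscav_file(0, shape, seed = 1)
  ser <- suppressWarnings(process_series(list(vs), model, c(250, 400)))
  expect_equal(ser$concentration_nM, 0)
  expect_equal(trace_metadata(ser)$floored_points, 1L)
  empty <- process_series(list(), model, c(250, 400))
  expect_equal(nrow(empty), 0)
  bad <- model
  bad$valid <- FALSE
  expect_error(process_series(list(vs), bad, c(250, 400)),
               class = "serovolt_validation_error")
})
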