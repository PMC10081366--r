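test_that("dose converts to initial peritoneal concentration by unit algebra", {
  p <- synthetic_fcm_rates(dose_mg_kg = 10)
  # 0.8 * 0.2 mg / (324.4 g/mol * 2 mL) = 2.466e5 nM
  expect_equal(dose_to_initial_peritoneal_concentration(p),
               0.8 * 0.2e-3 / 324.4 / 2e-3 * 1e9, tolerance = 1e-12)
  expect_equal(dose_to_initial_peritoneal_concentration(p), 2.466e5,
               tolerance = 1e-3)
  expect_equal(dose_to_initial_peritoneal_concentration(
    synthetic_fcm_rates(dose_mg_kg = 0)), 0)
  # linearity in dose
  p3 <- synthetic_fcm_rates(dose_mg_kg = 30)
  expect_equal(dose_to_initial_peritoneal_concentration(p3),
               3 * dose_to_initial_peritoneal_concentration(p),
               tolerance = 1e-12)
})

test_that("all-zero rate constants leave the depot untouched", {
  p <- fcm_params(0, 0, 0, 0, 0, 0, dose_mg_kg = 10)
  traj <- fcm_simulate(p, duration = 30, dt = 0.05)
  c0 <- dose_to_initial_peritoneal_concentration(p)
  expect_equal(traj$C_peritoneum_nM, rep(c0, nrow(traj)), tolerance = 1e-12)
  expect_true(all(traj$C_plasma_nM == 0))
  expect_true(all(traj$C_brain_nM == 0))
  expect_true(all(traj$C_periphery_nM == 0))
})

test_that("absorption-only kinetics follow the single-exponential solution", {
  p <- fcm_params(k01 = 0.2, 0, 0, 0, 0, 0, dose_mg_kg = 10)
  traj <- fcm_simulate(p, duration = 60, dt = 0.01)
  c0 <- dose_to_initial_peritoneal_concentration(p)
  expect_equal(traj$C_peritoneum_nM, c0 * exp(-0.2 * traj$time_min),
               tolerance = 1e-8)
  # the amount lost by the depot reappears in plasma exactly
  vols_L <- p$volumes_mL / 1000
  lost <- (c0 - traj$C_peritoneum_nM) * vols_L[["peritoneum"]]
  gained <- traj$C_plasma_nM * vols_L[["plasma"]]
  expect_equal(gained, lost, tolerance = 1e-8)
})

test_that("total drug amount is conserved when secretion is off", {
  p <- synthetic_fcm_rates(dose_mg_kg = 10)
  p$k10 <- 0
  traj <- fcm_simulate(p, duration = 240, dt = 0.01)
  total <- attr(traj, "total_amount_nmol")
  expect_lt(max(abs(total - total[1])) / total[1], 1e-4)
})

test_that("cumulative secreted amount never exceeds the bioavailable dose", {
  p <- synthetic_fcm_rates(dose_mg_kg = 10)
  traj <- fcm_simulate(p, duration = 240, dt = 0.02)
  sec <- secreted_amount(traj)
  dose_nmol <- p$bioavailability * p$dose_mg_kg * p$body_weight_g / 1000 *
    1e6 / p$molecular_weight
  expect_true(all(sec$secreted_nmol >= -1e-9))
  expect_true(all(sec$secreted_nmol <= dose_nmol + 1e-9))
  expect_true(all(diff(sec$secreted_nmol) >= -1e-12))
})

test_that("amount-conserving trajectories match an independent lsoda solve", {
  p <- synthetic_fcm_rates(dose_mg_kg = 3)
  traj <- fcm_simulate(p, duration = 120, dt = 0.01, output_every = 1)
  ref <- fcm_reference_solution(p, traj$time_min)
  for (j in 1:4) {
    expect_equal(as.matrix(traj[, j + 1])[, 1], unname(ref[, j]),
                 tolerance = 1e-6)
  }
})

test_that("the printed-equation variants differ and the repaired one balances", {
  p <- synthetic_fcm_rates(dose_mg_kg = 10)
  rep_traj <- fcm_simulate(p, duration = 60, dt = 0.02,
                           mode = "concentration", variant = "repaired")
  asp_traj <- fcm_simulate(p, duration = 60, dt = 0.02,
                           mode = "concentration", variant = "as_printed")
  # k12 != k13 here, so the duplicated-term reading changes plasma kinetics
  expect_gt(max(abs(rep_traj$C_plasma_nM - asp_traj$C_plasma_nM)), 0)
  # with k12 == k13 both readings coincide
  p2 <- fcm_params(0.1, 0.03, 0.15, 0.15, 0.15, 0.05, dose_mg_kg = 10)
  r2 <- fcm_simulate(p2, duration = 30, dt = 0.02, mode = "concentration",
                     variant = "repaired")
  a2 <- fcm_simulate(p2, duration = 30, dt = 0.02, mode = "concentration",
                     variant = "as_printed")
  expect_equal(r2$C_plasma_nM, a2$C_plasma_nM, tolerance = 1e-12)
})

test_that("apparent Km is the exact competitive-inhibition line", {
  expect_equal(apparent_km(2, 0, 1.1), 2)
  expect_equal(apparent_km(5, 1.1, 1.1), 10)  # doubling point at [I] = K_i
  expect_equal(apparent_km(2, 11, 1.1), 2 * (1 + 11 / 1.1), tolerance = 1e-12)
  # exactly linear with slope K_m / K_i
  conc <- seq(0, 100, by = 5)
  km <- apparent_km(2, conc, 1.1)
  slopes <- diff(km) / diff(conc)
  expect_equal(slopes, rep(2 / 1.1, length(slopes)), tolerance = 1e-12)
  expect_error(apparent_km(2, 1, 0), class = "serovolt_validation_error")
})

test_that("peak brain concentration increases strictly with dose", {
  peaks <- purrr::map_dbl(c(1, 3, 10, 30), function(d) {
    max(fcm_simulate(synthetic_fcm_rates(dose_mg_kg = d),
                     duration = 120, dt = 0.05)$C_brain_nM)
  })
  expect_true(all(diff(peaks) > 0))
})

test_that("post-drug predictions reduce to control at zero brain drug", {
  ctrl <- control_params()
  p <- synthetic_fcm_rates(dose_mg_kg = 0)
  traj <- fcm_simulate(p, duration = 60, dt = 0.05)
  pred <- predict_post_drug_trace(ctrl, traj, 30, duration = 20)
  base <- mm_simulate(ctrl, stim_protocol(), duration = 20)
  expect_equal(pred$concentration_nM, base$concentration_nM, tolerance = 1e-12)
  expect_error(predict_post_drug_trace(ctrl, traj, 500),
               class = "serovolt_range_error")
})

test_that("higher brain drug prolongs clearance monotonically", {
  ctrl <- control_params()
  p <- synthetic_fcm_rates(dose_mg_kg = 10)
  traj <- fcm_simulate(p, duration = 60, dt = 0.05)
  cb <- brain_concentration_at(traj, 30)
  halves <- purrr::map_dbl(c(cb, 2 * cb), function(conc) {
    km <- apparent_km(ctrl$K_m1, conc, p$K_i)
    tr <- mm_simulate(modify_params(ctrl, K_m1 = km), stim_protocol(),
                      duration = 25)
    fit_half_life(tr, detect_amp_max(tr)$t_peak)$t_half
  })
  base_tr <- mm_simulate(ctrl, stim_protocol(), duration = 25)
  base_half <- fit_half_life(base_tr, detect_amp_max(base_tr)$t_peak)$t_half
  expect_gt(halves[1], base_half)
  expect_gt(halves[2], halves[1])
})

test_that("the temporo-dose grid is complete and ordered in dose", {
  ctrl <- control_params()
  pbd <- purrr::map(c(1, 10), ~ synthetic_fcm_rates(dose_mg_kg = .x))
  grid <- temporo_dose_grid(ctrl, pbd, times_min = c(5, 30), duration = 20)
  expect_equal(nrow(grid$summary), 4)
  by_time <- dplyr::group_by(grid$summary, time_min)
  ordered <- dplyr::summarise(by_time,
    ok = all(diff(km_app_ratio[order(dose_mg_kg)]) >= 0))
  expect_true(all(ordered$ok))
  expect_error(temporo_dose_grid(ctrl, list(), times_min = 5),
               class = "serovolt_validation_error")
  expect_error(temporo_dose_grid(ctrl, pbd[c(1, 1)], times_min = 5),
               class = "serovolt_validation_error")
})
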