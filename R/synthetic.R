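#' Specification of a synthetic basal serotonin series
#'
#' Generative form for ambient-serotonin FSCAV series: a constant baseline,
#' a single sinusoid in the physiological 6-10 minute period band, AR(1)
#' noise, and an optional piecewise-linear post-drug ramp. One sample per
#' 60 s measurement cycle, matching the FSCAV acquisition.
#'
#' @param baseline_nM Ambient level, nM (default 60, a typical hippocampal
#'   basal serotonin scale).
#' @param oscillation_period_min Oscillation period, min; `NULL` draws one
#'   uniformly from `period_bounds` under the generation seed.
#' @param period_bounds Admissible period range, min (c(6, 10)).
#' @param oscillation_amplitude_nM Sinusoid amplitude, nM.
#' @param phase Sinusoid phase, rad.
#' @param drug_onset_min Ramp start, min (`Inf` = no drug).
#' @param drug_ramp_slope_nM_min Post-onset ramp slope, nM/min.
#' @param noise_sd_nM Marginal SD of the AR(1) noise, nM.
#' @param ar1_coefficient AR(1) coefficient in (-1, 1).
#' @param duration_min Series duration, min.
#' @return A `basal_spec` object.
#' @export
basal_spec <- function(baseline_nM = 60, oscillation_period_min = NULL,
                       period_bounds = c(6, 10),
                       oscillation_amplitude_nM = 5, phase = 0,
                       drug_onset_min = Inf, drug_ramp_slope_nM_min = 0,
                       noise_sd_nM = 2, ar1_coefficient = 0.5,
                       duration_min = 120) {
  if (!is.null(oscillation_period_min) &&
      (oscillation_period_min < period_bounds[1] ||
       oscillation_period_min > period_bounds[2])) {
    rlang::abort("oscillation period outside the configured bounds",
                 class = "serovolt_validation_error")
  }
  if (abs(ar1_coefficient) >= 1) {
    rlang::abort("AR(1) coefficient must lie in (-1, 1)",
                 class = "serovolt_validation_error")
  }
  stopifnot(baseline_nM >= 0, oscillation_amplitude_nM >= 0,
            noise_sd_nM >= 0, duration_min > 0)
  structure(list(baseline_nM = baseline_nM,
                 oscillation_period_min = oscillation_period_min,
                 period_bounds = period_bounds,
                 oscillation_amplitude_nM = oscillation_amplitude_nM,
                 phase = phase,
                 drug_onset_min = drug_onset_min,
                 drug_ramp_slope_nM_min = drug_ramp_slope_nM_min,
                 noise_sd_nM = noise_sd_nM,
                 ar1_coefficient = ar1_coefficient,
                 duration_min = duration_min,
                 sampling_period_s = 60),
            class = "basal_spec")
}

#' Simulate a basal (FSCAV) serotonin series
#'
#' `baseline + sinusoid + AR(1) noise + ramp`, sampled once per minute. The
#' ground-truth spec (including the realised oscillation period when it was
#' drawn) is stored in the series metadata. A duration shorter than one
#' oscillation period triggers a warning, not an error.
#'
#' @param spec A [basal_spec()].
#' @param seed Integer seed; all randomness (period draw, noise) is local
#'   to this call.
#' @return An [fscav_series()] of `floor(duration_min)` samples.
#' @export
#' @examples
#' s <- simulate_basal_series(basal_spec(oscillation_period_min = 8), seed = 1)
#' nrow(s)  # 120
simulate_basal_series <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "basal_spec"))
  n <- floor(spec$duration_min * 60 / spec$sampling_period_s)
  t_min <- seq_len(n) - 1
  withr::with_seed(seed, {
    period <- spec$oscillation_period_min %||%
      stats::runif(1, spec$period_bounds[1], spec$period_bounds[2])
    if (spec$duration_min < period) {
      rlang::warn("series shorter than one oscillation period",
                  class = "serovolt_short_series_warning")
    }
    osc <- spec$oscillation_amplitude_nM *
      sin(2 * pi * t_min / period + spec$phase)
    noise <- numeric(n)
    if (spec$noise_sd_nM > 0) {
      phi <- spec$ar1_coefficient
      innov_sd <- spec$noise_sd_nM * sqrt(1 - phi^2)
      e <- stats::rnorm(n, 0, innov_sd)
      noise[1] <- stats::rnorm(1, 0, spec$noise_sd_nM)
      if (n > 1) for (i in 2:n) noise[i] <- phi * noise[i - 1] + e[i]
    }
    ramp <- pmax(0, t_min - spec$drug_onset_min) * spec$drug_ramp_slope_nM_min
    fscav_series(t_min, spec$baseline_nM + osc + noise + ramp,
                 metadata = list(spec = spec, realised_period_min = period,
                                 seed = seed))
  })
}

#' Simulate an evoked FSCV trace with known ground truth
#'
#' Explicit-Euler forward solution of the dual-uptake model under the given
#' stimulation protocol, resampled to 10 Hz, plus white measurement noise.
#' With `noise_sd = 0` the output equals [mm_simulate()] on the same grid.
#'
#' @param params An [mm_params()].
#' @param protocol A [stim_protocol()].
#' @param dt Euler step, s.
#' @param duration Trace duration, s.
#' @param noise_sd Gaussian measurement noise SD, nM.
#' @param seed Integer seed (local to this call).
#' @param stim_start_s Stimulus onset, s.
#' @return A [concentration_trace()]; metadata carries the ground-truth
#'   parameters, protocol, noise level and seed.
#' @export
simulate_evoked_trace <- function(params, protocol = stim_protocol(),
                                  dt = 0.01, duration = 30, noise_sd = 0,
                                  seed = 1L, stim_start_s = 5) {
  tr <- mm_simulate(params, protocol, dt = dt, duration = duration,
                    stim_start_s = stim_start_s, resample_hz = 10)
  if (noise_sd > 0) {
    noisy <- withr::with_seed(seed,
      tr$concentration_nM + stats::rnorm(nrow(tr), 0, noise_sd))
    tr$concentration_nM <- noisy
  }
  meta <- trace_metadata(tr)
  meta$protocol <- protocol
  meta$noise_sd <- noise_sd
  meta$seed <- seed
  attr(tr, "metadata") <- meta
  tr
}

#' Shape specification for synthetic cyclic voltammograms
#'
#' Phenomenological single-sweep model: a smooth capacitive background
#' (polynomial in normalised sample position) plus a Gaussian Faradaic
#' serotonin peak whose integrated charge is `calibration_slope` pC per nM
#' of analyte. No electrochemical physics is simulated.
#'
#' @param peak_center Peak centre, sample index.
#' @param peak_width Gaussian SD, samples. `peak_center +/- 3*peak_width`
#'   must fit inside the sweep.
#' @param calibration_slope Peak charge per concentration, pC/nM (> 0).
#' @param background_coefficients Polynomial coefficients (intercept first)
#'   in the normalised coordinate `s/sweep_length`, nA.
#' @param noise_sd Additive current noise SD, nA.
#' @param sweep_length Samples per sweep.
#' @param sample_rate_hz Digitisation rate, Hz.
#' @return A `cv_shape_spec` object.
#' @export
cv_shape_spec <- function(peak_center = 310, peak_width = 15,
                          calibration_slope = 0.4,
                          background_coefficients = c(20, -30, 25),
                          noise_sd = 0, sweep_length = 1000,
                          sample_rate_hz = 5e5) {
  if (calibration_slope <= 0) {
    rlang::abort("calibration_slope must be positive",
                 class = "serovolt_validation_error")
  }
  if (peak_center - 3 * peak_width < 1 ||
      peak_center + 3 * peak_width > sweep_length) {
    rlang::abort("peak_center +/- 3*peak_width must lie inside the sweep",
                 class = "serovolt_validation_error")
  }
  structure(list(peak_center = peak_center, peak_width = peak_width,
                 calibration_slope = calibration_slope,
                 background_coefficients = background_coefficients,
                 noise_sd = noise_sd, sweep_length = sweep_length,
                 sample_rate_hz = sample_rate_hz),
            class = "cv_shape_spec")
}

cv_background <- function(shape) {
  s <- (seq_len(shape$sweep_length) - 1) / shape$sweep_length
  as.numeric(outer(s, seq_along(shape$background_coefficients) - 1, `^`) %*%
               shape$background_coefficients)
}

cv_peak <- function(shape, concentration) {
  s <- seq_len(shape$sweep_length)
  # Gaussian whose time-integral (nA * s, converted to pC) equals
  # calibration_slope * concentration
  area_nAs <- shape$calibration_slope * concentration / 1e3
  amp <- area_nAs / (shape$peak_width * sqrt(2 * pi) / shape$sample_rate_hz)
  amp * exp(-(s - shape$peak_center)^2 / (2 * shape$peak_width^2))
}

#' Synthesize single-sweep voltammograms at known concentrations
#'
#' One sweep per requested concentration: background polynomial plus a
#' Gaussian Faradaic peak whose integrated charge is exactly
#' `calibration_slope * concentration` (plus optional noise). Charge is
#' therefore linear in concentration by construction.
#'
#' @param concentrations_nM Non-negative concentrations, one per sweep.
#' @param shape A [cv_shape_spec()].
#' @param seed Integer seed for the noise.
#' @return A [voltammogram_set()]; ground truth in metadata.
#' @export
synthesize_voltammograms <- function(concentrations_nM, shape = cv_shape_spec(),
                                     seed = 1L) {
  stopifnot(inherits(shape, "cv_shape_spec"))
  if (any(concentrations_nM < 0)) {
    rlang::abort("concentrations must be non-negative",
                 class = "serovolt_validation_error")
  }
  bg <- cv_background(shape)
  mat <- withr::with_seed(seed, {
    t(vapply(concentrations_nM, function(cc) {
      sweep_i <- bg + cv_peak(shape, cc)
      if (shape$noise_sd > 0) {
        sweep_i <- sweep_i + stats::rnorm(shape$sweep_length, 0, shape$noise_sd)
      }
      sweep_i
    }, numeric(shape$sweep_length)))
  })
  voltammogram_set(mat, sample_rate_hz = shape$sample_rate_hz,
                   metadata = list(shape = shape,
                                   concentrations_nM = concentrations_nM,
                                   seed = seed))
}

#' Synthesize one FSCAV measurement file
#'
#' A full 60-second acquisition: `n_pre` pure-background sweeps (the
#' background-subtraction segment and adsorption period) followed by
#' post-adsorption sweeps carrying the Faradaic peak. The metadata records
#' `adsorption_boundary` so [select_measurement_cv()] picks the third
#' post-adsorption CV.
#'
#' @param concentration_nM Ambient concentration encoded in the file.
#' @param shape A [cv_shape_spec()].
#' @param seed Integer seed.
#' @param n_pre Background/adsorption sweeps before the boundary (default 12).
#' @param n_post Post-adsorption sweeps (default 5).
#' @return A [voltammogram_set()].
#' @export
synthesize_fscav_file <- function(concentration_nM, shape = cv_shape_spec(),
                                  seed = 1L, n_pre = 12, n_post = 5) {
  stopifnot(n_pre >= 10, n_post >= 3)
  vs <- synthesize_voltammograms(
    c(rep(0, n_pre), rep(concentration_nM, n_post)), shape, seed)
  vs$metadata$adsorption_boundary <- n_pre + 1L
  vs$metadata$concentration_nM <- concentration_nM
  vs
}
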