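# zero-phase frequency-domain Butterworth low-pass along matrix columns,
# with symmetric (reflective) padding to suppress edge transients
fft_butterworth_cols <- function(mat, fs, fc, order) {
  n <- nrow(mat)
  pad <- mat[c(seq_len(n), rev(seq_len(n))), , drop = FALSE]
  np <- 2L * n
  f <- fs * c(0:(ceiling(np / 2) - 1), -(floor(np / 2):1)) / np
  gain <- 1 / sqrt(1 + (f / fc)^(2 * order))
  sp <- stats::mvfft(pad) * gain
  Re(stats::mvfft(sp, inverse = TRUE))[seq_len(n), , drop = FALSE] / np
}

#' Low-pass filter a colour plot (2D Butterworth)
#'
#' Separable frequency-domain Butterworth low-pass of the current matrix:
#' 3rd order with a 37.5 kHz cutoff along the intra-sweep (fast) axis and a
#' 2.5 Hz cutoff along the across-sweep (slow, 10 Hz) axis by default. The
#' filter is applied as a real magnitude response in the FFT domain with
#' symmetric padding, so it is zero-phase and has unit DC gain.
#'
#' @param vset A [voltammogram_set()] with at least 2 sweeps.
#' @param fast_cutoff_hz Cutoff along a sweep, Hz.
#' @param slow_cutoff_hz Cutoff across sweeps, Hz.
#' @param order Butterworth order (3).
#' @return A filtered `voltammogram_set` of identical dimensions.
#' @export
filter_color_plot <- function(vset, fast_cutoff_hz = 37.5e3,
                              slow_cutoff_hz = 2.5, order = 3) {
  stopifnot(inherits(vset, "voltammogram_set"))
  if (nrow(vset$current) < 2) {
    rlang::abort("slow-axis filtering needs at least 2 sweeps",
                 class = "serovolt_validation_error")
  }
  m <- vset$current
  # fast axis: filter along each sweep (rows) -> transpose so sweeps are columns
  m <- t(fft_butterworth_cols(t(m), vset$sample_rate_hz, fast_cutoff_hz, order))
  # slow axis: filter each potential point across sweeps
  m <- fft_butterworth_cols(m, vset$sweep_rate_hz, slow_cutoff_hz, order)
  out <- vset
  out$current <- m
  out$metadata$filtered <- TRUE
  out
}

#' Extract a calibrated concentration trace from a colour plot
#'
#' Reads the current at the analyte's oxidation-peak sample index on every
#' sweep, subtracts the mean of the first 10 sweeps (the pre-stimulation
#' background) and scales by an electrode calibration factor. The standard
#' serotonin factor on the Jackson waveform is 49.5 uM/nA; factors are
#' treated as opaque "concentration units per nA" scalars carrying a units
#' tag, because published constants mix uM/nA and nM/nA across waveforms.
#'
#' @param vset A [voltammogram_set()] with >= 10 sweeps.
#' @param peak_index Sample index of the Faradaic peak on the sweep (1-based).
#' @param calibration_factor Concentration units per nA.
#' @param factor_units Units tag recorded in the metadata (e.g. "uM_per_nA").
#' @param stim_start,stim_end Optional stimulation window annotation, s.
#' @return A [concentration_trace()] sampled at the sweep rate.
#' @export
extract_calibrated_trace <- function(vset, peak_index, calibration_factor,
                                     factor_units = "nM_per_nA",
                                     stim_start = NA_real_,
                                     stim_end = NA_real_) {
  stopifnot(inherits(vset, "voltammogram_set"))
  if (peak_index < 1 || peak_index > ncol(vset$current)) {
    rlang::abort("peak_index outside the sweep",
                 class = "serovolt_validation_error")
  }
  if (nrow(vset$current) < 10) {
    rlang::abort("background subtraction needs at least 10 sweeps",
                 class = "serovolt_validation_error")
  }
  i_t <- vset$current[, peak_index]
  bg <- mean(i_t[1:10])
  conc <- (i_t - bg) * calibration_factor
  time_s <- (seq_along(i_t) - 1) / vset$sweep_rate_hz
  concentration_trace(time_s, conc, stim_start, stim_end,
                      metadata = list(peak_index = peak_index,
                                      calibration_factor = calibration_factor,
                                      factor_units = factor_units))
}

pre_stim_segment <- function(trace, min_baseline_s = 5) {
  sw <- stim_window(trace)
  if (any(is.na(sw))) {
    rlang::abort("trace must carry a stimulation window annotation",
                 class = "serovolt_validation_error")
  }
  pre <- trace$concentration_nM[trace$time_s < sw[1]]
  if (length(pre) < min_baseline_s / trace_dt(trace)) {
    rlang::abort(sprintf("need >= %g s of pre-stimulation baseline",
                         min_baseline_s),
                 class = "serovolt_validation_error")
  }
  pre
}

#' Detect the maximum evoked amplitude
#'
#' Finds local maxima of the trace between stimulation onset and
#' `search_window_s` seconds later, requires the excursion over the
#' pre-stimulation baseline mean to exceed `prominence_sd` baseline standard
#' deviations, and reports the highest qualifying maximum relative to
#' baseline. A trace without a qualifying maximum yields a not-found row
#' (`found = FALSE`) rather than an error.
#'
#' @param trace A [concentration_trace()] with >= 5 s pre-stimulation
#'   baseline.
#' @param search_window_s Search extent after stimulation onset, s (30).
#' @param prominence_sd Baseline-SD multiple a peak must exceed (3).
#' @return One-row tibble: `t_peak` (s), `amp_max` (nM over baseline),
#'   `baseline` (nM), `found`.
#' @export
detect_amp_max <- function(trace, search_window_s = 30, prominence_sd = 3) {
  pre <- pre_stim_segment(trace)
  base_mean <- mean(pre)
  base_sd <- stats::sd(pre)
  sw <- stim_window(trace)
  in_win <- which(trace$time_s >= sw[1] &
                    trace$time_s <= sw[1] + search_window_s)
  x <- trace$concentration_nM
  maxima <- in_win[in_win > 1 & in_win < length(x)]
  maxima <- maxima[x[maxima] > x[maxima - 1] & x[maxima] >= x[maxima + 1]]
  heights <- x[maxima] - base_mean
  ok <- heights > prominence_sd * base_sd & heights > 0
  if (!any(ok)) {
    return(tibble::tibble(t_peak = NA_real_, amp_max = NA_real_,
                          baseline = base_mean, found = FALSE))
  }
  best <- maxima[ok][which.max(heights[ok])]
  tibble::tibble(t_peak = trace$time_s[best],
                 amp_max = x[best] - base_mean,
                 baseline = base_mean, found = TRUE)
}

#' Exponential clearance fit and half-life
#'
#' Fits `C(t) = C_peak * exp(-k (t - t_peak)) + baseline` to the post-peak
#' decay by least squares (the amplitude and offset are profiled out
#' analytically for each candidate rate, leaving a 1-D optimisation over
#' `k`), and reports the half-life `t_half = ln(2) / k`. The offset term
#' absorbs a non-zero ambient level; pin it to zero with
#' `pin_baseline = TRUE` for the textbook two-parameter form.
#'
#' @param trace A [concentration_trace()].
#' @param t_peak Decay start (the amplitude peak time), s.
#' @param window_s Length of decay segment fitted, s (`Inf` = to the end).
#' @param pin_baseline Force the offset to 0.
#' @return One-row tibble: `k` (1/s), `t_half` (s), `C_peak`, `baseline`,
#'   `rmse`, `degenerate` (TRUE when the segment does not decay).
#' @export
fit_half_life <- function(trace, t_peak, window_s = Inf, pin_baseline = FALSE) {
  seg <- trace[trace$time_s >= t_peak &
                 trace$time_s <= t_peak + window_s, ]
  if (nrow(seg) < 2 / trace_dt(trace)) {
    rlang::abort("need >= 2 s of post-peak data",
                 class = "serovolt_validation_error")
  }
  tt <- seg$time_s - t_peak
  y <- seg$concentration_nM
  sse_at <- function(logk) {
    e <- exp(-exp(logk) * tt)
    if (pin_baseline) {
      a <- sum(e * y) / sum(e * e)
      sum((y - a * e)^2)
    } else {
      fit <- stats::lm.fit(cbind(e, 1), y)
      sum(fit$residuals^2)
    }
  }
  opt <- stats::optimize(sse_at, c(log(1e-4), log(1e3)))
  k <- exp(opt$minimum)
  e <- exp(-k * tt)
  if (pin_baseline) {
    a <- sum(e * y) / sum(e * e)
    b <- 0
  } else {
    cf <- stats::lm.fit(cbind(e, 1), y)$coefficients
    a <- cf[1]
    b <- cf[2]
  }
  at_edge <- opt$minimum < log(1e-4) + 1e-3 || opt$minimum > log(1e3) - 1e-3
  degenerate <- !is.finite(a) || a <= 0 || at_edge
  tibble::tibble(k = k, t_half = if (degenerate) NA_real_ else log(2) / k,
                 C_peak = unname(a), baseline = unname(b),
                 rmse = sqrt(opt$objective / length(y)),
                 degenerate = degenerate)
}

#' Serotonin inhibition amplitude below baseline
#'
#' Largest negative deflection below the pre-stimulation baseline mean
#' within `window_s` seconds of stimulation onset, reported as a positive
#' magnitude; 0 when the trace never dips.
#'
#' @param trace A [concentration_trace()] with >= 5 s baseline.
#' @param window_s Search extent after stimulation onset, s (20).
#' @return Inhibition amplitude, nM (>= 0).
#' @export
detect_inhibition <- function(trace, window_s = 20) {
  pre <- pre_stim_segment(trace)
  base_mean <- mean(pre)
  sw <- stim_window(trace)
  win <- trace$concentration_nM[trace$time_s >= sw[1] &
                                  trace$time_s <= sw[1] + window_s]
  max(0, base_mean - min(win))
}
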