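#' Bandpass-filter a basal serotonin series
#'
#' Zero-phase (forward-backward) 3rd-order Butterworth bandpass, default
#' passband 0.0008-0.005 Hz: the low cutoff removes slow drug-driven drifts
#' of the ambient level, the high cutoff removes measurement noise, leaving
#' the 6-10 minute oscillation band. Forward-backward application squares
#' the magnitude response, so the effective rolloff is twice the nominal
#' order. The output is zero-mean, so its values are deviations from the
#' ambient level rather than absolute concentrations.
#'
#' @param series An [fscav_series()] (one sample per 60 s).
#' @param low_hz,high_hz Passband edges, Hz.
#' @param order Butterworth order (3).
#' @return A zero-mean `fscav_series` of deviations, nM.
#' @export
bandpass <- function(series, low_hz = 0.0008, high_hz = 0.005, order = 3) {
  stopifnot(inherits(series, "fscav_series"))
  fs <- 1 / 60
  if (nrow(series) < 3 / (low_hz * 60)) {
    rlang::warn(sprintf(
      "series (%d min) is shorter than three periods of the low cutoff; output is unreliable",
      nrow(series)), class = "serovolt_short_series_warning")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  # centre (exact DC removal) and reflect-pad to suppress the forward-backward
  # filter's edge transients, then crop back to the original span
  x <- series$concentration_nM - mean(series$concentration_nM)
  n <- length(x)
  pad <- c(rev(x), x, rev(x))
  y <- signal::filtfilt(bf, pad)[(n + 1):(2 * n)]
  md <- trace_metadata(series)
  md$bandpassed <- c(low_hz, high_hz)
  fscav_series(series$time_min, y, metadata = md)
}

#' Autocorrelation of a basal series
#'
#' Sample autocorrelation at lags 0..`max_lag`,
#' \deqn{r_p = \frac{\sum_{i=1}^{N-p} (X_i - \bar X)(X_{i+p} - \bar X)}
#'   {\sum_{i=1}^{N} (X_i - \bar X)^2}}
#' with the full-series mean in both factors and the full sum of squares in
#' the denominator, so that `r_0 = 1` exactly.
#'
#' @param series An [fscav_series()] (or plain numeric vector).
#' @param max_lag Largest lag, samples (one sample = 1 min); must be below
#'   the series length.
#' @return Tibble `lag_min`, `r`.
#' @export
autocorrelation <- function(series, max_lag = min(60L, nrow_or_len(series) - 1L)) {
  x <- series_values(series)
  n <- length(x)
  if (max_lag >= n) {
    rlang::abort("max_lag must be smaller than the series length",
                 class = "serovolt_validation_error")
  }
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) {
    rlang::abort("zero-variance series: autocorrelation undefined",
                 class = "serovolt_undefined_correlation_error")
  }
  r <- vapply(0:max_lag, function(p) {
    i <- seq_len(n - p)
    sum(xc[i] * xc[i + p]) / denom
  }, numeric(1))
  tibble::tibble(lag_min = 0:max_lag, r = r)
}

#' Sliding-window lagged correlation
#'
#' Pearson correlation between a window of `window_min` samples starting at
#' time t and the equally long window lagged by p samples, each centred on
#' its own mean:
#' \deqn{r_{t,p} = \frac{\sum_s (X_s - \bar X_t)(X_{s+p} - \bar X_{t+p})}
#'   {\sqrt{\sum_s (X_s - \bar X_t)^2 \sum_s (X_{s+p} - \bar X_{t+p})^2}}}
#' Zero-variance windows yield `NA` entries rather than errors.
#'
#' @param series An [fscav_series()] or numeric vector.
#' @param window_min Window length in samples/minutes (default 25).
#' @param lags Integer lags in samples (default 0 to a third of the series).
#' @return A numeric matrix, rows = window start times (min), columns =
#'   lags; class `swc_matrix`.
#' @export
sliding_window_correlation <- function(series, window_min = 25, lags = NULL) {
  x <- series_values(series)
  n <- length(x)
  if (is.null(lags)) lags <- 0:max(1L, floor(n / 3))
  max_lag <- max(lags)
  if (window_min + max_lag > n) {
    rlang::abort("window plus maximum lag exceeds the series span",
                 class = "serovolt_validation_error")
  }
  n_starts <- n - window_min - max_lag + 1L
  m <- matrix(NA_real_, n_starts, length(lags),
              dimnames = list(start_min = seq_len(n_starts) - 1L,
                              lag_min = lags))
  for (ti in seq_len(n_starts)) {
    w1 <- x[ti:(ti + window_min - 1L)]
    s1 <- stats::sd(w1)
    for (li in seq_along(lags)) {
      w2 <- x[(ti + lags[li]):(ti + lags[li] + window_min - 1L)]
      s2 <- stats::sd(w2)
      if (s1 > 0 && s2 > 0) m[ti, li] <- stats::cor(w1, w2)
    }
  }
  structure(m, class = c("swc_matrix", "matrix", "array"),
            window_min = window_min)
}

#' Welch power spectral density of a basal series
#'
#' Averaged modified periodogram: the series is split into overlapping
#' segments (default length half the series, 50% overlap), each segment is
#' mean-detrended, tapered with a periodic Hann window and Fourier
#' transformed; one-sided periodograms are averaged across segments. The
#' zero-frequency bin is dropped (segments are detrended anyway) so the
#' grid starts at the first resolvable frequency.
#'
#' @param series An [fscav_series()] or numeric vector sampled at `fs`.
#' @param segment_length Samples per segment; default `floor(N/2)`.
#' @param overlap Fractional segment overlap (0.5).
#' @param fs Sampling rate, Hz (1/60 for FSCAV).
#' @return A `psd_result` tibble: `frequency_hz`, `power`,
#'   `normalized_power` (sums to 1), with the power-weighted mean frequency
#'   in attribute `weighted_frequency`.
#' @export
welch_psd <- function(series, segment_length = NULL, overlap = 0.5,
                      fs = 1 / 60) {
  x <- series_values(series)
  n <- length(x)
  nseg <- segment_length %||% floor(n / 2)
  if (nseg < 4 || nseg > n) {
    rlang::abort("segment length must be >= 4 samples and fit in the series",
                 class = "serovolt_validation_error")
  }
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq(1L, n - nseg + 1L, by = step)
  if (length(starts) < 2) {
    rlang::abort("series too short for two Welch segments",
                 class = "serovolt_validation_error")
  }
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / nseg))  # periodic Hann
  scale <- fs * sum(w^2)
  n_freq <- floor(nseg / 2)
  acc <- numeric(n_freq + 1L)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg))^2 / scale
    one <- sp[seq_len(n_freq + 1L)]
    dbl <- 2:(n_freq + if (nseg %% 2 == 0) 0L else 1L)
    one[dbl] <- 2 * one[dbl]
    acc <- acc + one
  }
  pow <- (acc / length(starts))[-1]  # drop the DC bin
  freq <- (seq_len(n_freq)) * fs / nseg
  psd_result(freq, pow)
}

psd_result <- function(frequency_hz, power) {
  stopifnot(all(diff(frequency_hz) > 0), all(power >= 0))
  total <- sum(power)
  norm <- if (total > 0) power / total else rep(NA_real_, length(power))
  out <- tibble::tibble(frequency_hz = frequency_hz, power = power,
                        normalized_power = norm)
  structure(out,
            weighted_frequency = if (total > 0) sum(frequency_hz * norm) else NA_real_,
            class = c("psd_result", class(out)))
}

#' Power-weighted mean frequency of a spectrum
#'
#' The scalar `WF = sum_i f_i * P_i / sum_i P_i`: the centre of mass of the
#' power spectrum, used to detect wholesale displacement of slow-oscillation
#' power. With `normalize = FALSE` the raw `sum_i f_i * P_i` is returned
#' instead (an alternative reading of "sum of power-weighted frequencies").
#'
#' @param psd A `psd_result` from [welch_psd()].
#' @param normalize Divide by total power (default TRUE).
#' @return Frequency, Hz.
#' @export
weighted_frequency <- function(psd, normalize = TRUE) {
  stopifnot(inherits(psd, "psd_result"))
  total <- sum(psd$power)
  if (total == 0) {
    rlang::abort("all-zero spectrum: weighted frequency undefined",
                 class = "serovolt_undefined_error")
  }
  if (normalize) sum(psd$frequency_hz * psd$power) / total
  else sum(psd$frequency_hz * psd$power)
}

#' Pre/post-drug weighted-frequency comparison
#'
#' For each animal's matched pre- and post-drug basal series: bandpass
#' (optional), Welch PSD, power-weighted mean frequency; report the
#' per-animal WF pair and delta plus the group mean delta. A positive group
#' delta (oscillations speeding up) is the Uptake-1-inhibition-like
#' direction; a negative delta is Uptake-2-like.
#'
#' @param pre_series,post_series Lists of [fscav_series()], matched by
#'   position (one element per animal).
#' @param bandpass_first Apply [bandpass()] before the PSD (default TRUE).
#' @param ... Passed to [welch_psd()].
#' @return A tibble `animal`, `wf_pre`, `wf_post`, `delta` with attributes
#'   `group_delta` (mean delta, Hz) and `direction`
#'   (`"uptake1-like"`, `"uptake2-like"` or `"none"`).
#' @export
compare_pre_post <- function(pre_series, post_series, bandpass_first = TRUE,
                             ...) {
  if (length(pre_series) != length(post_series)) {
    rlang::abort("pre and post lists must pair one series per animal",
                 class = "serovolt_pairing_error")
  }
  wf_of <- function(s) {
    if (bandpass_first) s <- suppressWarnings(bandpass(s))
    weighted_frequency(welch_psd(s, ...))
  }
  out <- tibble::tibble(animal = seq_along(pre_series),
                        wf_pre = purrr::map_dbl(pre_series, wf_of),
                        wf_post = purrr::map_dbl(post_series, wf_of))
  out$delta <- out$wf_post - out$wf_pre
  gd <- mean(out$delta)
  structure(out, group_delta = gd,
            direction = if (gd > 0) "uptake1-like"
                        else if (gd < 0) "uptake2-like" else "none")
}

series_values <- function(x) {
  if (inherits(x, "fscav_series")) x$concentration_nM else as.numeric(x)
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
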