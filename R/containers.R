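#' Evoked concentration-versus-time trace
#'
#' The currency of FSCV analysis: a uniformly sampled concentration time
#' series (nM against seconds, nominally 10 Hz) with an optional electrical
#' stimulation window annotation and a free-form provenance/metadata list.
#' Returned as a tibble of class `concentration_trace` with columns
#' `time_s` and `concentration_nM`.
#'
#' @param time_s Numeric vector of sample times in seconds, uniformly spaced.
#' @param concentration_nM Numeric vector of concentrations in nM, same length.
#' @param stim_start,stim_end Stimulation window in seconds, or `NA` when the
#'   trace carries no stimulus. The window must lie inside the time span.
#' @param metadata Named list of provenance (ground-truth parameters for
#'   synthetic traces, calibration settings for extracted ones).
#'
#' @return A `concentration_trace` tibble.
#' @export
#' @examples
#' tr <- concentration_trace(seq(0, 2, 0.1), rep(0, 21))
#' tr
concentration_trace <- function(time_s, concentration_nM,
                                stim_start = NA_real_, stim_end = NA_real_,
                                metadata = list()) {
  stopifnot(length(time_s) == length(concentration_nM), length(time_s) >= 2)
  check_uniform(time_s, "time_s")
  if (!is.na(stim_start) && !is.na(stim_end)) {
    if (stim_start > stim_end ||
        stim_start < time_s[1] || stim_end > time_s[length(time_s)]) {
      rlang::abort("stimulation window must lie inside the trace time span",
                   class = "serovolt_validation_error")
    }
  }
  out <- tibble::tibble(time_s = as.numeric(time_s),
                        concentration_nM = as.numeric(concentration_nM))
  structure(out,
            stim_start = stim_start, stim_end = stim_end,
            metadata = metadata,
            class = c("concentration_trace", class(out)))
}

#' Basal (ambient) serotonin series from FSCAV
#'
#' Minute-resolution ambient concentration series: one point per 60 s
#' measurement cycle. Stored as a tibble of class `fscav_series` with columns
#' `time_min` and `concentration_nM`.
#'
#' @param time_min Sample times in minutes, spaced 1 min apart.
#' @param concentration_nM Concentrations in nM (non-negative).
#' @param metadata Named list of provenance.
#' @return An `fscav_series` tibble.
#' @export
fscav_series <- function(time_min, concentration_nM, metadata = list()) {
  stopifnot(length(time_min) == length(concentration_nM))
  if (length(time_min) >= 2) check_uniform(time_min, "time_min")
  out <- tibble::tibble(time_min = as.numeric(time_min),
                        concentration_nM = as.numeric(concentration_nM))
  structure(out, metadata = metadata,
            class = c("fscav_series", class(out)))
}

#' Set of single-sweep voltammograms (a colour plot)
#'
#' A sequence of current-versus-sample voltammetric sweeps, stored as a
#' numeric matrix with one row per sweep, plus acquisition metadata: the
#' within-sweep sampling rate (fast axis), the sweep repetition rate
#' (slow axis, 10 Hz for FSCV) and free-form provenance.
#'
#' @param current Numeric matrix, rows = successive sweeps, columns = sample
#'   index along the potential sweep; units nA.
#' @param sample_rate_hz Digitisation rate along a sweep (fast axis), Hz.
#' @param sweep_rate_hz Sweep repetition rate (slow axis), Hz. Default 10.
#' @param metadata Named list; FSCAV sets use `adsorption_boundary`, the
#'   1-based row index of the first sweep after the controlled-adsorption
#'   period.
#' @return A `voltammogram_set` object.
#' @export
voltammogram_set <- function(current, sample_rate_hz = 5e5, sweep_rate_hz = 10,
                             metadata = list()) {
  current <- as.matrix(current)
  if (!is.numeric(current)) {
    rlang::abort("current must be a numeric matrix",
                 class = "serovolt_validation_error")
  }
  stopifnot(sample_rate_hz > 0, sweep_rate_hz > 0)
  structure(list(current = unname(current),
                 sample_rate_hz = sample_rate_hz,
                 sweep_rate_hz = sweep_rate_hz,
                 metadata = metadata),
            class = "voltammogram_set")
}

#' @export
print.voltammogram_set <- function(x, ...) {
  cat(sprintf("<voltammogram_set> %d sweeps x %d samples (%.3g kHz fast, %g Hz sweep)\n",
              nrow(x$current), ncol(x$current),
              x$sample_rate_hz / 1e3, x$sweep_rate_hz))
  invisible(x)
}

#' @export
dim.voltammogram_set <- function(x) dim(x$current)

# uniform-sampling guard shared by the trace containers
check_uniform <- function(t, what, tol = 1e-6) {
  d <- diff(t)
  if (any(d <= 0) || (max(d) - min(d)) > tol * max(abs(d))) {
    rlang::abort(paste0(what, " must be strictly increasing and uniformly sampled"),
                 class = "serovolt_validation_error")
  }
  invisible(TRUE)
}

trace_dt <- function(trace) {
  diff(trace$time_s[1:2])
}

#' Read / write concentration traces and basal series as CSV
#'
#' Plain UTF-8 comma-separated files with a header row
#' (`time_s,concentration_nM` for FSCV traces, `time_min,concentration_nM`
#' for FSCAV series). Lines starting with `#` carry provenance comments and
#' are ignored on read.
#'
#' @param trace A `concentration_trace` (or `fscav_series` for the series
#'   variants).
#' @param path File path.
#' @param comments Character vector written as `#`-prefixed header lines.
#' @return `read_trace_csv()` returns a `concentration_trace`;
#'   `read_series_csv()` an `fscav_series`; the writers return `path`
#'   invisibly.
#' @export
write_trace_csv <- function(trace, path, comments = character()) {
  write_commented_csv(as.data.frame(trace)[c("time_s", "concentration_nM")],
                      path, comments)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  concentration_trace(df$time_s, df$concentration_nM)
}

#' @rdname write_trace_csv
#' @export
write_series_csv <- function(trace, path, comments = character()) {
  write_commented_csv(as.data.frame(trace)[c("time_min", "concentration_nM")],
                      path, comments)
}

#' @rdname write_trace_csv
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  fscav_series(df$time_min, df$concentration_nM)
}

#' Read / write a voltammogram set as a CSV matrix
#'
#' Rows are sweeps, columns sample indices; acquisition metadata travels in
#' `#key: value` comment lines at the top of the file.
#'
#' @param vset A `voltammogram_set`.
#' @param path File path.
#' @return `read_voltammograms_csv()` returns a `voltammogram_set`;
#'   the writer returns `path` invisibly.
#' @export
write_voltammograms_csv <- function(vset, path) {
  meta <- c(sprintf("sample_rate_hz: %.10g", vset$sample_rate_hz),
            sprintf("sweep_rate_hz: %.10g", vset$sweep_rate_hz))
  if (!is.null(vset$metadata$adsorption_boundary)) {
    meta <- c(meta, sprintf("adsorption_boundary: %d",
                            as.integer(vset$metadata$adsorption_boundary)))
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#", meta), con)
  utils::write.table(vset$current, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_voltammograms_csv
#' @export
read_voltammograms_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#", "", h), ":\\s*")[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- as.numeric(kv[2])
  }
  mat <- as.matrix(utils::read.csv(text = lines[!grepl("^#", lines)],
                                   header = FALSE))
  md <- list()
  if (!is.null(meta$adsorption_boundary)) {
    md$adsorption_boundary <- as.integer(meta$adsorption_boundary)
  }
  voltammogram_set(mat,
                   sample_rate_hz = meta$sample_rate_hz %||% 5e5,
                   sweep_rate_hz = meta$sweep_rate_hz %||% 10,
                   metadata = md)
}

write_commented_csv <- function(df, path, comments = character()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Metadata accessors
#'
#' @param x A trace, series or voltammogram set.
#' @return The metadata list (or stimulation window endpoints for
#'   `stim_window()`, a length-2 numeric).
#' @export
trace_metadata <- function(x) attr(x, "metadata") %||% x$metadata

#' @rdname trace_metadata
#' @export
stim_window <- function(x) c(attr(x, "stim_start"), attr(x, "stim_end"))
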