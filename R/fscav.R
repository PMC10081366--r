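# composite Simpson's rule on uniformly sampled values; falls back to a
# trapezoid on the final interval when the point count is even
simpson_integral <- function(y, dx) {
  n <- length(y)
  if (n < 2) return(0)
  if (n == 2) return(dx * (y[1] + y[2]) / 2)
  if (n %% 2 == 1) {
    i <- seq(1, n - 2, by = 2)
    sum(dx / 3 * (y[i] + 4 * y[i + 1] + y[i + 2]))
  } else {
    simpson_integral(y[seq_len(n - 1)], dx) + dx * (y[n - 1] + y[n]) / 2
  }
}

#' Average-background subtraction for an FSCAV sweep sequence
#'
#' Averages the first 10 cyclic voltammograms and subtracts that mean sweep
#' from every sweep in the set.
#'
#' @param vset A [voltammogram_set()] with >= 11 sweeps.
#' @return A background-subtracted `voltammogram_set` of identical shape.
#' @export
background_subtract <- function(vset) {
  stopifnot(inherits(vset, "voltammogram_set"))
  if (nrow(vset$current) < 11) {
    rlang::abort("background subtraction needs at least 11 sweeps",
                 class = "serovolt_validation_error")
  }
  bg <- colMeans(vset$current[1:10, , drop = FALSE])
  out <- vset
  out$current <- sweep(vset$current, 2, bg)
  out$metadata$background_subtracted <- TRUE
  out
}

#' Select the measurement cyclic voltammogram
#'
#' The third CV after the controlled-adsorption period carries the
#' concentration estimate. The set's metadata must name
#' `adsorption_boundary`, the 1-based index of the first post-adsorption
#' sweep; the sweep two rows later (the third post-adsorption CV) is
#' returned.
#'
#' @param vset A [voltammogram_set()].
#' @return Numeric vector: the selected sweep's current samples (nA).
#' @export
select_measurement_cv <- function(vset) {
  stopifnot(inherits(vset, "voltammogram_set"))
  b <- vset$metadata$adsorption_boundary
  if (is.null(b)) {
    rlang::abort("metadata must record adsorption_boundary",
                 class = "serovolt_metadata_error")
  }
  idx <- b + 2L
  if (idx > nrow(vset$current)) {
    rlang::abort("fewer than 3 sweeps after the adsorption boundary",
                 class = "serovolt_validation_error")
  }
  vset$current[idx, ]
}

# strict local minima of a vector (sign change of the first difference)
local_minima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] < x[i - 1] & x[i] <= x[i + 1]]
}

#' Simpson's-rule charge under the Faradaic peak
#'
#' Locates the global maximum of the sweep inside `search_window`, takes the
#' nearest flanking local minima (found on a 5-point moving-average smoothed
#' copy, used only for bound detection) as integration bounds, integrates
#' the raw current between them with composite Simpson's rule, and subtracts
#' the capacitive baseline charge under the straight line joining the two
#' endpoint currents. Bounds fall back to the window edges, with a warning,
#' when no flanking minimum exists.
#'
#' @param cv Numeric vector: one sweep's current samples, nA.
#' @param search_window Integer range (1-based sample indices) containing the
#'   peak, e.g. `c(250, 400)`.
#' @param sample_rate_hz Digitisation rate along the sweep, Hz.
#' @param smooth_points Moving-average width for minima detection (5).
#' @return Charge in pC (nA x us scale handled internally).
#' @export
integrate_peak <- function(cv, search_window = c(1, length(cv)),
                           sample_rate_hz = 5e5, smooth_points = 5) {
  stopifnot(is.numeric(cv), length(search_window) == 2)
  lo <- max(1L, as.integer(search_window[1]))
  hi <- min(length(cv), as.integer(search_window[2]))
  if (hi - lo < 2) {
    rlang::abort("search window too narrow", class = "serovolt_validation_error")
  }
  sm <- stats::filter(cv, rep(1 / smooth_points, smooth_points), sides = 2)
  sm[is.na(sm)] <- cv[is.na(sm)]
  sm <- as.numeric(sm)
  peak <- lo - 1L + which.max(cv[lo:hi])
  mins <- local_minima(sm)
  left_candidates <- mins[mins >= lo & mins < peak]
  right_candidates <- mins[mins > peak & mins <= hi]
  fell_back <- FALSE
  left <- if (length(left_candidates)) max(left_candidates) else {
    fell_back <- TRUE
    lo
  }
  right <- if (length(right_candidates)) min(right_candidates) else {
    fell_back <- TRUE
    hi
  }
  if (fell_back) {
    rlang::warn("no flanking local minimum inside the window; using window edges",
                class = "serovolt_bounds_warning")
  }
  y <- cv[left:right]
  dx <- 1 / sample_rate_hz
  total <- simpson_integral(y, dx)
  base <- (y[1] + y[length(y)]) / 2 * dx * (length(y) - 1)
  (total - base) * 1e3  # nA * s = nC -> pC
}

#' Electrode calibration by ordinary least squares
#'
#' Regresses integrated charge on standard concentration (the in vitro
#' standards are typically 10, 25, 50 and 100 nM) and stores slope,
#' intercept and r-squared. A non-positive slope marks the model invalid.
#'
#' @param standards A data frame / tibble with columns `concentration_nM`
#'   and `charge_pC` (>= 2 distinct concentrations).
#' @return A `calibration_model` object.
#' @export
fit_calibration <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("concentration_nM", "charge_pC") %in% names(standards)))
  if (length(unique(standards$concentration_nM)) < 2) {
    rlang::abort("calibration needs >= 2 distinct standard concentrations",
                 class = "serovolt_rank_error")
  }
  fit <- stats::lm(charge_pC ~ concentration_nM, data = standards)
  cf <- stats::coef(fit)
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 r_squared = summary(fit)$r.squared,
                 standards = tibble::as_tibble(standards),
                 valid = unname(cf[2]) > 0),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> charge = %.4g pC/nM * conc + %.4g pC (r^2 = %.4f)%s\n",
              x$slope, x$intercept, x$r_squared,
              if (x$valid) "" else "  [INVALID: non-positive slope]"))
  invisible(x)
}

#' Process an FSCAV file sequence into a basal concentration series
#'
#' Per 60-second file: background subtraction, third-CV selection, Simpson
#' charge integration and calibration,
#' `concentration = (charge - intercept) / slope`, floored at 0 (with a
#' count of floored points in the metadata). Timestamps advance one minute
#' per file.
#'
#' @param vsets Ordered list of [voltammogram_set()]s, one per measurement
#'   cycle.
#' @param model A valid [fit_calibration()] model.
#' @param search_window Peak search window passed to [integrate_peak()].
#' @return An [fscav_series()].
#' @export
process_series <- function(vsets, model, search_window) {
  stopifnot(inherits(model, "calibration_model"))
  if (!model$valid) {
    rlang::abort("calibration model is invalid (non-positive slope)",
                 class = "serovolt_validation_error")
  }
  if (length(vsets) == 0) {
    return(fscav_series(numeric(0), numeric(0),
                        metadata = list(model = model)))
  }
  floored <- 0L
  conc <- purrr::imap_dbl(vsets, function(v, i) {
    q <- tryCatch({
      cv <- select_measurement_cv(background_subtract(v))
      integrate_peak(cv, search_window, sample_rate_hz = v$sample_rate_hz)
    }, error = function(e) {
      rlang::abort(sprintf("file %d: %s", i, conditionMessage(e)),
                   class = "serovolt_stage_error", parent = e)
    })
    c_hat <- (q - model$intercept) / model$slope
    if (c_hat < 0) {
      floored <<- floored + 1L
      0
    } else c_hat
  })
  fscav_series(seq_along(conc) - 1, conc,
               metadata = list(model = model, floored_points = floored,
                               search_window = search_window))
}
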