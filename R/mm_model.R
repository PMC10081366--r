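#' Parameters of the dual-uptake Michaelis-Menten release/clearance model
#'
#' Extracellular serotonin dynamics are modelled as
#' \deqn{dC/dt = R(t)\,(1 - A(t)) - \alpha \frac{V_{max1} C}{K_{m1} + C}
#'   - \beta \frac{V_{max2} C}{K_{m2} + C}}
#' with two saturable clearance routes: Uptake 1, high-affinity/low-capacity
#' (serotonin transporters; `V_max1`, `K_m1`) and Uptake 2,
#' low-affinity/high-capacity (OCT/DAT/NET/PMAT; `V_max2`, `K_m2`).
#'
#' The evoked release envelope `R(t)` rises as
#' `R_max * (1 - exp(-(t - t_on)/tau_on))` during the stimulus and relaxes
#' exponentially with time constant `tau_off` afterwards; a constant basal
#' release `R_basal` may sustain a non-zero ambient level. The autoreceptor
#' occupancy `A(t)` is a delayed Hill function of concentration,
#' `A_max * C(t - A_delay)^h / (A_ec50^h + C(t - A_delay)^h)`, bounded in
#' `[0, 1)`; it defaults to off (`A_max = 0`).
#'
#' Defaults for the kinetic constants are the control parameterisation used
#' throughout the modelled-trace work: `K_m1 = 2` nM, `V_max1 = 12` nM/s,
#' `K_m2 = 170` nM, `V_max2 = 780` nM/s. `alpha` and `beta` are fixed
#' multipliers of the two clearance terms (default 1; non-identifiable
#' jointly with `V_max`, so excluded from fitting).
#'
#' @param R_max Peak evoked release rate, nM/s.
#' @param tau_on,tau_off Release envelope rise / relaxation constants, s.
#' @param R_basal Constant basal release rate, nM/s.
#' @param A_max,A_ec50,A_hill,A_delay Autoreceptor occupancy ceiling
#'   (dimensionless, < 1), half-occupancy concentration (nM), Hill exponent
#'   and transmission delay (s).
#' @param alpha,beta Clearance-term coefficients (dimensionless, >= 0).
#' @param V_max1,K_m1 Uptake 1 capacity (nM/s) and Michaelis constant (nM).
#' @param V_max2,K_m2 Uptake 2 capacity (nM/s) and Michaelis constant (nM).
#' @param C0 Initial concentration, nM; `NULL` starts at the resting steady
#'   state implied by `R_basal`.
#' @return An `mm_params` object (named list).
#' @export
#' @examples
#' p <- mm_params()
#' uptake_rate(2, p)   # half-saturated Uptake 1 plus a sliver of Uptake 2
mm_params <- function(R_max = 250, tau_on = 0.3, tau_off = 0.3, R_basal = 0,
                      A_max = 0, A_ec50 = 50, A_hill = 2, A_delay = 0.3,
                      alpha = 1, beta = 1,
                      V_max1 = 12, K_m1 = 2, V_max2 = 780, K_m2 = 170,
                      C0 = NULL) {
  p <- list(R_max = R_max, tau_on = tau_on, tau_off = tau_off,
            R_basal = R_basal,
            A_max = A_max, A_ec50 = A_ec50, A_hill = A_hill, A_delay = A_delay,
            alpha = alpha, beta = beta,
            V_max1 = V_max1, K_m1 = K_m1, V_max2 = V_max2, K_m2 = K_m2,
            C0 = C0)
  validate_mm_params(p)
  structure(p, class = "mm_params")
}

validate_mm_params <- function(p) {
  nn <- c("R_max", "tau_on", "tau_off", "R_basal", "A_ec50", "A_delay",
          "alpha", "beta", "V_max1", "K_m1", "V_max2", "K_m2")
  bad <- nn[vapply(nn, function(f) !is.finite(p[[f]]) || p[[f]] < 0, logical(1))]
  if (length(bad)) {
    rlang::abort(paste("non-negative finite values required for:",
                       paste(bad, collapse = ", ")),
                 class = "serovolt_validation_error")
  }
  if (p$A_max < 0 || p$A_max >= 1) {
    rlang::abort("A_max must lie in [0, 1)", class = "serovolt_validation_error")
  }
  if (!is.null(p$C0) && (!is.finite(p$C0) || p$C0 < 0)) {
    rlang::abort("C0 must be a non-negative concentration",
                 class = "serovolt_validation_error")
  }
  invisible(p)
}

#' @export
print.mm_params <- function(x, ...) {
  cat("<mm_params>\n")
  cat(sprintf("  Uptake 1: V_max1 = %g nM/s, K_m1 = %g nM (alpha = %g)\n",
              x$V_max1, x$K_m1, x$alpha))
  cat(sprintf("  Uptake 2: V_max2 = %g nM/s, K_m2 = %g nM (beta = %g)\n",
              x$V_max2, x$K_m2, x$beta))
  cat(sprintf("  Release:  R_max = %g nM/s (tau_on %g s, tau_off %g s), R_basal = %g nM/s\n",
              x$R_max, x$tau_on, x$tau_off, x$R_basal))
  if (x$A_max > 0) {
    cat(sprintf("  Autoreceptor: A_max = %g, EC50 = %g nM, h = %g, delay = %g s\n",
                x$A_max, x$A_ec50, x$A_hill, x$A_delay))
  }
  invisible(x)
}

#' Total Michaelis-Menten clearance rate at a concentration
#'
#' Sum of the two saturable uptake terms,
#' `alpha*V_max1*C/(K_m1 + C) + beta*V_max2*C/(K_m2 + C)`. Strictly
#' increasing in `C` and bounded above by `alpha*V_max1 + beta*V_max2`.
#'
#' @param C Concentration(s), nM (>= 0). Vectorised.
#' @param params An [mm_params()].
#' @return Clearance rate(s), nM/s.
#' @export
uptake_rate <- function(C, params) {
  stopifnot(inherits(params, "mm_params"))
  if (any(C < 0)) {
    rlang::abort("concentration must be non-negative",
                 class = "serovolt_validation_error")
  }
  params$alpha * params$V_max1 * C / (params$K_m1 + C) +
    params$beta * params$V_max2 * C / (params$K_m2 + C)
}

#' Steady-state concentration under constant release
#'
#' Solves `uptake_rate(C) = R_const` for the unique non-negative root. With
#' both uptake terms active this is the positive root of a quadratic; it
#' exists only when `R_const` is below the total clearance capacity
#' `alpha*V_max1 + beta*V_max2`.
#'
#' @param R_const Constant release rate, nM/s.
#' @param params An [mm_params()].
#' @return Steady-state concentration, nM.
#' @export
mm_steady_state <- function(R_const, params) {
  stopifnot(inherits(params, "mm_params"), R_const >= 0)
  if (R_const == 0) return(0)
  a1 <- params$alpha * params$V_max1
  a2 <- params$beta * params$V_max2
  k1 <- params$K_m1
  k2 <- params$K_m2
  if (R_const >= a1 + a2) {
    rlang::abort(sprintf(
      "release %g nM/s meets or exceeds total clearance capacity %g nM/s: no steady state",
      R_const, a1 + a2), class = "serovolt_no_steady_state_error")
  }
  # a1 C (k2+C) + a2 C (k1+C) = R (k1+C)(k2+C)
  A <- a1 + a2 - R_const
  B <- a1 * k2 + a2 * k1 - R_const * (k1 + k2)
  D <- -R_const * k1 * k2
  roots <- suppressWarnings((-B + c(1, -1) * sqrt(B^2 - 4 * A * D)) / (2 * A))
  root <- roots[roots >= 0 & is.finite(roots)]
  max(root)
}

# evoked release envelope over a fine time grid
release_envelope <- function(times, params, stim_start, stim_end) {
  r <- rep(params$R_basal, length(times))
  if (stim_end > stim_start && params$R_max > 0) {
    during <- times >= stim_start & times <= stim_end
    if (params$tau_on > 0) {
      r[during] <- r[during] +
        params$R_max * (1 - exp(-(times[during] - stim_start) / params$tau_on))
    } else {
      r[during] <- r[during] + params$R_max
    }
    r_end <- if (params$tau_on > 0) {
      params$R_max * (1 - exp(-(stim_end - stim_start) / params$tau_on))
    } else params$R_max
    after <- times > stim_end
    if (params$tau_off > 0) {
      r[after] <- r[after] +
        r_end * exp(-(times[after] - stim_end) / params$tau_off)
    }
  }
  r
}

#' Forward simulation of the dual-uptake model (explicit Euler)
#'
#' Integrates the release/clearance ODE with the explicit Euler method on a
#' fine fixed grid and resamples the solution to the acquisition grid
#' (10 Hz by default) by nearest-step lookup. Steps that would undershoot
#' zero are clamped at 0 and counted (`clamp_events` in the trace metadata)
#' rather than silently clipped.
#'
#' @param params An [mm_params()].
#' @param protocol A [stim_protocol()]; its duration sets the release window.
#' @param dt Euler step, s (default 0.01).
#' @param duration Total simulated time, s.
#' @param stim_start_s Stimulus onset relative to trace start, s.
#' @param resample_hz Output sampling rate, Hz; `NULL` returns the full
#'   Euler grid.
#' @return A [concentration_trace()] with the stimulation window annotated
#'   and ground-truth parameters in its metadata.
#' @export
#' @examples
#' tr <- mm_simulate(mm_params(), stim_protocol(), duration = 20)
#' max(tr$concentration_nM)
mm_simulate <- function(params, protocol = stim_protocol(), dt = 0.01,
                        duration = 30, stim_start_s = 5, resample_hz = 10) {
  stopifnot(inherits(params, "mm_params"), dt > 0, duration > 0)
  validate_mm_params(params)
  stim_start <- stim_start_s
  stim_end <- stim_start_s + protocol$duration_s
  if (stim_end > duration) {
    rlang::abort("trace duration must cover the stimulation window",
                 class = "serovolt_validation_error")
  }
  n <- floor(duration / dt) + 1L
  times <- (seq_len(n) - 1L) * dt
  rel <- release_envelope(times, params, stim_start, stim_end)
  c0 <- params$C0 %||% mm_steady_state(params$R_basal, params)
  conc <- numeric(n)
  conc[1] <- c0
  delay_steps <- as.integer(round(params$A_delay / dt))
  a_on <- params$A_max > 0
  a1 <- params$alpha * params$V_max1
  a2 <- params$beta * params$V_max2
  k1 <- params$K_m1
  k2 <- params$K_m2
  a_max <- params$A_max
  a_h <- params$A_hill
  ec_h <- params$A_ec50^params$A_hill
  clamped <- 0L
  for (i in seq_len(n - 1L)) {
    Ci <- conc[i]
    A <- 0
    if (a_on) {
      j <- i - delay_steps
      Cd <- if (j >= 1L) conc[j] else c0
      if (Cd > 0) {
        ch <- Cd^a_h
        A <- a_max * ch / (ec_h + ch)
      }
    }
    dC <- rel[i] * (1 - A) - a1 * Ci / (k1 + Ci) - a2 * Ci / (k2 + Ci)
    Cn <- Ci + dt * dC
    if (!is.finite(Cn)) {
      rlang::abort(sprintf("non-finite concentration at step %d (t = %.3f s); reduce dt",
                           i, times[i]),
                   class = "serovolt_integration_error")
    }
    if (Cn < 0) {
      Cn <- 0
      clamped <- clamped + 1L
    }
    conc[i + 1L] <- Cn
  }
  meta <- list(params = params, dt = dt, clamp_events = clamped,
               solver = "euler")
  if (is.null(resample_hz)) {
    return(concentration_trace(times, conc, stim_start, stim_end, meta))
  }
  out_t <- seq(0, duration, by = 1 / resample_hz)
  idx <- pmin(n, pmax(1L, as.integer(round(out_t / dt)) + 1L))
  concentration_trace(out_t, conc[idx], stim_start, stim_end, meta)
}

#' The three canonical uptake-inhibition scenarios plus control
#'
#' Forward-simulates the control parameterisation and its three classic
#' perturbations: competitive Uptake 2 inhibition (`K_m2` x 10), competitive
#' Uptake 1 inhibition (`K_m1` x 10), and mixed Uptake 1 inhibition
#' (`K_m1` x 10 with `V_max1` halved). Every perturbation slows clearance,
#' so each perturbed trace has a longer half-life than control.
#'
#' @param control Control [mm_params()].
#' @param protocol A [stim_protocol()].
#' @param ... Passed to [mm_simulate()] (`dt`, `duration`, ...).
#' @return A tibble with columns `scenario`, `time_s`, `concentration_nM`;
#'   scenario levels `control`, `km2_x10`, `km1_x10`, `km1_x10_vmax1_x0.5`.
#'   The per-scenario parameter sets are attached as attribute `params`.
#' @export
mm_scenarios <- function(control = mm_params(), protocol = stim_protocol(),
                         ...) {
  stopifnot(inherits(control, "mm_params"))
  scen <- list(
    control = control,
    km2_x10 = modify_params(control, K_m2 = control$K_m2 * 10),
    km1_x10 = modify_params(control, K_m1 = control$K_m1 * 10),
    `km1_x10_vmax1_x0.5` = modify_params(control,
                                         K_m1 = control$K_m1 * 10,
                                         V_max1 = control$V_max1 * 0.5))
  traces <- purrr::map(scen, mm_simulate, protocol = protocol, ...)
  out <- dplyr::bind_rows(purrr::imap(traces, function(tr, nm) {
    tibble::tibble(scenario = nm, time_s = tr$time_s,
                   concentration_nM = tr$concentration_nM)
  }))
  out$scenario <- factor(out$scenario, levels = names(scen))
  structure(out, params = scen, traces = traces,
            stim_start = attr(traces[[1]], "stim_start"),
            stim_end = attr(traces[[1]], "stim_end"))
}

#' Copy a parameter set with selected fields replaced
#'
#' @param params An [mm_params()].
#' @param ... Named fields to overwrite.
#' @return A new `mm_params`.
#' @export
modify_params <- function(params, ...) {
  repl <- rlang::list2(...)
  p <- unclass(params)
  p[names(repl)] <- repl
  validate_mm_params(p)
  structure(p, class = "mm_params")
}
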