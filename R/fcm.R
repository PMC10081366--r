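#' Parameters of the four-compartment escitalopram pharmacokinetic model
#'
#' An intraperitoneal dose distributes between four compartments -
#' peritoneum, plasma, brain extracellular space and periphery - with
#' first-order exchange. Plasma protein binding (fraction `P_B`) and
#' escitalopram binding to brain SERTs (fraction `SERT_B`) reduce the
#' freely exchanging fraction; `k10` is secretion from plasma.
#'
#' No authoritative rate-constant set ships with the package (the published
#' values live in a figure table that is not transcribed here): the six rate
#' constants are required arguments. [synthetic_fcm_rates()] provides a
#' documented synthetic set for examples and tests.
#'
#' @param k01,k10,k12,k21,k13,k31 First-order rate constants, 1/min:
#'   peritoneum to plasma, plasma secretion, plasma to brain, brain to
#'   plasma, plasma to periphery, periphery to plasma.
#' @param P_B Plasma protein-bound fraction (0.56).
#' @param SERT_B SERT-bound fraction in brain (0.15).
#' @param bioavailability Fraction of the dose reaching the peritoneal
#'   depot (0.80).
#' @param volumes_mL Named numeric: peritoneum, plasma, brain, periphery
#'   volumes in mL (defaults 2, 2, 0.41, 15).
#' @param dose_mg_kg Dose in mg per kg body weight.
#' @param body_weight_g Body weight, g (default 20 g mouse).
#' @param molecular_weight Drug molecular weight, g/mol (escitalopram free
#'   base, 324.4).
#' @param K_i Competitive inhibition constant at SERT, nM (1.1).
#' @return An `fcm_params` object.
#' @export
fcm_params <- function(k01, k10, k12, k21, k13, k31,
                       P_B = 0.56, SERT_B = 0.15, bioavailability = 0.80,
                       volumes_mL = c(peritoneum = 2, plasma = 2,
                                      brain = 0.41, periphery = 15),
                       dose_mg_kg = 10, body_weight_g = 20,
                       molecular_weight = 324.4, K_i = 1.1) {
  rates <- c(k01 = k01, k10 = k10, k12 = k12, k21 = k21, k13 = k13, k31 = k31)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    rlang::abort("rate constants must be non-negative and finite",
                 class = "serovolt_validation_error")
  }
  for (f in c(P_B, SERT_B, bioavailability)) {
    if (!is.finite(f) || f < 0 || f > 1) {
      rlang::abort("binding fractions and bioavailability must lie in [0, 1]",
                   class = "serovolt_validation_error")
    }
  }
  if (length(volumes_mL) != 4 || any(volumes_mL <= 0)) {
    rlang::abort("four positive compartment volumes required",
                 class = "serovolt_validation_error")
  }
  if (molecular_weight <= 0) {
    rlang::abort("molecular weight must be positive",
                 class = "serovolt_validation_error")
  }
  if (dose_mg_kg < 0 || body_weight_g <= 0 || K_i <= 0) {
    rlang::abort("dose must be >= 0, body weight and K_i > 0",
                 class = "serovolt_validation_error")
  }
  structure(list(k01 = k01, k10 = k10, k12 = k12, k21 = k21,
                 k13 = k13, k31 = k31,
                 P_B = P_B, SERT_B = SERT_B,
                 bioavailability = bioavailability,
                 volumes_mL = stats::setNames(as.numeric(volumes_mL),
                                              c("peritoneum", "plasma",
                                                "brain", "periphery")),
                 dose_mg_kg = dose_mg_kg, body_weight_g = body_weight_g,
                 molecular_weight = molecular_weight, K_i = K_i),
            class = "fcm_params")
}

#' A synthetic rate-constant set for examples and tests
#'
#' SYNTHETIC values, not a published parameterisation: chosen once to give a
#' plausible murine escitalopram profile (fast peritoneal absorption, plasma
#' elimination half-life of tens of minutes, brain peak a few tens of
#' minutes post-injection).
#'
#' @param ... Overrides passed on to [fcm_params()].
#' @return An `fcm_params`.
#' @export
synthetic_fcm_rates <- function(...) {
  fcm_params(k01 = 0.10, k10 = 0.03, k12 = 0.10, k21 = 0.15,
             k13 = 0.20, k31 = 0.05, ...)
}

#' Initial peritoneal concentration implied by a dose
#'
#' Converts an intraperitoneal dose to the starting drug concentration in
#' the peritoneal compartment:
#' `bioavailability * dose * body_weight / (MW * V_peritoneum)`, in nM.
#'
#' @param params An [fcm_params()].
#' @return Concentration, nM.
#' @export
#' @examples
#' p <- synthetic_fcm_rates(dose_mg_kg = 10)
#' dose_to_initial_peritoneal_concentration(p)  # ~2.47e5 nM
dose_to_initial_peritoneal_concentration <- function(params) {
  stopifnot(inherits(params, "fcm_params"))
  dose_mg <- params$dose_mg_kg * params$body_weight_g / 1000
  nmol <- params$bioavailability * dose_mg * 1e6 / params$molecular_weight
  nmol / (params$volumes_mL[["peritoneum"]] / 1000)
}

fcm_deriv <- function(y, p, mode, variant) {
  fP <- 1 - p$P_B     # free fraction in plasma
  fS <- 1 - p$SERT_B  # free fraction in brain
  if (mode == "amount") {
    # y = amounts (nmol); every outflow of one compartment is an inflow of
    # another, so total amount is conserved when k10 = 0
    out1 <- (p$k10 + p$k12 + p$k13) * y[2] * fP
    c(-p$k01 * y[1],
      p$k01 * y[1] - out1 + p$k21 * y[3] * fS + p$k31 * y[4],
      p$k12 * y[2] * fP - p$k21 * y[3] * fS,
      p$k13 * y[2] * fP - p$k31 * y[4])
  } else {
    # y = concentrations (nM), exchanged without volume scaling, following
    # the printed equations; "repaired" reads the duplicated plasma k12 term
    # as the k13 plasma-to-periphery flow
    k_extra <- if (variant == "repaired") p$k13 else p$k12
    c(-p$k01 * y[1],
      p$k01 * y[1] - (p$k10 + p$k12) * y[2] * fP + p$k21 * y[3] * fS -
        k_extra * y[2] * fP + p$k31 * y[4],
      p$k12 * y[2] * fP - p$k21 * y[3] * fS,
      p$k13 * y[2] * fP - p$k31 * y[4])
  }
}

#' Simulate the four-compartment model
#'
#' Integrates the compartmental system with classic fixed-step fourth-order
#' Runge-Kutta. Two formulations are available:
#' \describe{
#'   \item{`amount-conserving` (default)}{tracks drug amounts (nmol) so that
#'     inter-compartment flows conserve mass exactly; concentrations are
#'     reported as amount / compartment volume. With `k10 = 0` the total
#'     amount is constant to numerical precision.}
#'   \item{`concentration`}{integrates the concentration equations exactly
#'     as printed, which exchange concentrations without volume scaling.
#'     `variant = "repaired"` resolves the duplicated plasma-outflow term as
#'     the plasma-to-periphery flow (k13), making the system consistent with
#'     the brain and periphery equations; `variant = "as_printed"` keeps the
#'     duplicate for fidelity audits.}
#' }
#'
#' @param params An [fcm_params()].
#' @param duration Simulated time, min.
#' @param dt Integration step, min (default 0.01).
#' @param mode `"amount-conserving"` or `"concentration"`.
#' @param variant Equation variant for concentration mode: `"repaired"` or
#'   `"as_printed"`.
#' @param output_every Output grid spacing, min (default 0.1).
#' @return An `fcm_trajectory` tibble: `time_min`, `C_peritoneum_nM`,
#'   `C_plasma_nM`, `C_brain_nM`, `C_periphery_nM`, with `params`, `mode`
#'   and (amount mode) `total_amount_nmol` in its attributes.
#' @export
fcm_simulate <- function(params, duration = 240, dt = 0.01,
                         mode = c("amount-conserving", "concentration"),
                         variant = c("repaired", "as_printed"),
                         output_every = 0.1) {
  stopifnot(inherits(params, "fcm_params"), duration > 0, dt > 0)
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  c0 <- dose_to_initial_peritoneal_concentration(params)
  vols_L <- params$volumes_mL / 1000
  internal_mode <- if (mode == "amount-conserving") "amount" else "conc"
  y <- if (internal_mode == "amount") c(c0 * vols_L[[1]], 0, 0, 0) else c(c0, 0, 0, 0)
  n <- floor(duration / dt)
  keep <- max(1L, as.integer(round(output_every / dt)))
  n_out <- floor(n / keep) + 1L
  out <- matrix(NA_real_, n_out, 4)
  out_t <- numeric(n_out)
  out[1, ] <- y
  j <- 1L
  for (i in seq_len(n)) {
    k1 <- fcm_deriv(y, params, internal_mode, variant)
    k2 <- fcm_deriv(y + dt / 2 * k1, params, internal_mode, variant)
    k3 <- fcm_deriv(y + dt / 2 * k2, params, internal_mode, variant)
    k4 <- fcm_deriv(y + dt * k3, params, internal_mode, variant)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(y))) {
      rlang::abort(sprintf("non-finite compartment state at step %d (t = %.2f min)",
                           i, i * dt),
                   class = "serovolt_integration_error")
    }
    if (i %% keep == 0L) {
      j <- j + 1L
      out[j, ] <- y
      out_t[j] <- i * dt
    }
  }
  out <- out[seq_len(j), , drop = FALSE]
  out_t <- out_t[seq_len(j)]
  conc <- if (internal_mode == "amount") {
    sweep(out, 2, as.numeric(vols_L), "/")
  } else out
  traj <- tibble::tibble(time_min = out_t,
                         C_peritoneum_nM = conc[, 1],
                         C_plasma_nM = conc[, 2],
                         C_brain_nM = conc[, 3],
                         C_periphery_nM = conc[, 4])
  total <- if (internal_mode == "amount") rowSums(out) else NULL
  structure(traj, params = params, mode = mode, variant = variant,
            total_amount_nmol = total,
            class = c("fcm_trajectory", class(traj)))
}

#' Apparent Michaelis constant under competitive inhibition
#'
#' `K_m_app = K_m * (1 + inhibitor / K_i)`: a competitive inhibitor leaves
#' V_max untouched and inflates the substrate's apparent K_m linearly in
#' inhibitor concentration.
#'
#' @param K_m Uninhibited Michaelis constant, nM.
#' @param inhibitor_nM Inhibitor (escitalopram) concentration, nM. Vectorised.
#' @param K_i Inhibition constant, nM (> 0; escitalopram at SERT: 1.1).
#' @return Apparent K_m, nM.
#' @export
#' @examples
#' apparent_km(2, 11, 1.1)  # 24 nM
apparent_km <- function(K_m, inhibitor_nM, K_i = 1.1) {
  if (!is.finite(K_i) || K_i <= 0) {
    rlang::abort("K_i must be a positive concentration",
                 class = "serovolt_validation_error")
  }
  if (any(K_m < 0) || any(inhibitor_nM < 0)) {
    rlang::abort("concentrations must be non-negative",
                 class = "serovolt_validation_error")
  }
  K_m * (1 + inhibitor_nM / K_i)
}

#' Brain drug concentration at a time point
#'
#' Linear interpolation of the brain compartment curve.
#'
#' @param trajectory An [fcm_simulate()] result.
#' @param t_min Time post-injection, min (inside the trajectory span).
#' @return Concentration, nM.
#' @export
brain_concentration_at <- function(trajectory, t_min) {
  stopifnot(inherits(trajectory, "fcm_trajectory"))
  tr <- trajectory$time_min
  if (any(t_min < tr[1]) || any(t_min > tr[length(tr)])) {
    rlang::abort("requested time lies outside the simulated trajectory",
                 class = "serovolt_range_error")
  }
  stats::approx(tr, trajectory$C_brain_nM, xout = t_min)$y
}

#' Predicted evoked trace at a time after drug injection
#'
#' Substitutes the Uptake 1 Michaelis constant with its competitive-inhibition
#' apparent value at the simulated brain drug concentration,
#' `K_m1 -> apparent_km(K_m1, C_brain(t_post), K_i)`, and forward-simulates
#' the dual-uptake model with every other parameter at its control value.
#'
#' @param control Control [mm_params()].
#' @param trajectory An [fcm_simulate()] result.
#' @param t_post Time post-injection, min.
#' @param protocol A [stim_protocol()].
#' @param ... Passed to [mm_simulate()].
#' @return A [concentration_trace()]; its metadata records `C_brain_nM`,
#'   `K_m1_app` and `t_post_min`.
#' @export
predict_post_drug_trace <- function(control, trajectory, t_post,
                                    protocol = stim_protocol(), ...) {
  stopifnot(inherits(control, "mm_params"))
  cb <- brain_concentration_at(trajectory, t_post)
  ki <- attr(trajectory, "params")$K_i
  km_app <- apparent_km(control$K_m1, cb, ki)
  tr <- mm_simulate(modify_params(control, K_m1 = km_app), protocol, ...)
  meta <- attr(tr, "metadata")
  meta$C_brain_nM <- cb
  meta$K_m1_app <- km_app
  meta$t_post_min <- t_post
  attr(tr, "metadata") <- meta
  tr
}

#' Temporo-dose grid of predicted post-drug responses
#'
#' For every (dose, time) cell: simulate the compartmental model at that
#' dose, read the brain drug concentration at that time, inflate K_m1 to its
#' apparent value and forward-simulate the evoked response. Summaries report
#' the maximum amplitude, clearance half-life and the apparent-K_m fold
#' change against control. At fixed time the apparent-K_m ratio is
#' non-decreasing in dose.
#'
#' @param control Control [mm_params()].
#' @param params_by_dose List of [fcm_params()], one per dose (distinct
#'   doses).
#' @param times_min Numeric vector of post-injection times, min
#'   (default 5, 30, 60, 90, 120).
#' @param protocol A [stim_protocol()].
#' @param ... Passed to [mm_simulate()] for the per-cell traces.
#' @return A list with `summary` (tibble: dose_mg_kg, time_min, C_brain_nM,
#'   K_m1_app, km_app_ratio, amp_max, t_half, ratios vs the control trace)
#'   and `traces` (long tibble of every predicted trace plus control).
#' @export
temporo_dose_grid <- function(control, params_by_dose,
                              times_min = c(5, 30, 60, 90, 120),
                              protocol = stim_protocol(), ...) {
  if (length(params_by_dose) == 0 || length(times_min) == 0) {
    rlang::abort("dose and time grids must be non-empty",
                 class = "serovolt_validation_error")
  }
  doses <- purrr::map_dbl(params_by_dose, "dose_mg_kg")
  if (anyDuplicated(doses)) {
    rlang::abort("doses must be distinct", class = "serovolt_validation_error")
  }
  ctrl_trace <- mm_simulate(control, protocol, ...)
  ctrl_amp <- detect_amp_max(ctrl_trace)
  ctrl_half <- fit_half_life(ctrl_trace, ctrl_amp$t_peak)
  cells <- tidyr::expand_grid(dose_idx = seq_along(params_by_dose),
                              time_min = times_min)
  trajs <- purrr::map(params_by_dose, fcm_simulate,
                      duration = max(times_min) + 1)
  rows <- purrr::pmap(cells, function(dose_idx, time_min) {
    tr <- predict_post_drug_trace(control, trajs[[dose_idx]], time_min,
                                  protocol, ...)
    amp <- detect_amp_max(tr)
    half <- fit_half_life(tr, amp$t_peak)
    meta <- trace_metadata(tr)
    list(summary = tibble::tibble(
           dose_mg_kg = doses[dose_idx], time_min = time_min,
           C_brain_nM = meta$C_brain_nM, K_m1_app = meta$K_m1_app,
           km_app_ratio = meta$K_m1_app / control$K_m1,
           amp_max = amp$amp_max, t_half = half$t_half,
           amp_ratio = amp$amp_max / ctrl_amp$amp_max,
           t_half_ratio = half$t_half / ctrl_half$t_half),
         trace = tibble::tibble(dose_mg_kg = doses[dose_idx],
                                time_min = time_min,
                                time_s = tr$time_s,
                                concentration_nM = tr$concentration_nM))
  })
  list(summary = dplyr::bind_rows(purrr::map(rows, "summary")),
       traces = dplyr::bind_rows(
         tibble::tibble(dose_mg_kg = 0, time_min = NA_real_,
                        time_s = ctrl_trace$time_s,
                        concentration_nM = ctrl_trace$concentration_nM),
         dplyr::bind_rows(purrr::map(rows, "trace"))),
       control = list(trace = ctrl_trace, amp = ctrl_amp, half = ctrl_half))
}

#' Cumulative secreted amount over a trajectory
#'
#' Amount-conserving mode only: secreted = initial total amount minus the
#' total amount remaining in the four compartments.
#'
#' @param trajectory An amount-conserving [fcm_simulate()] result.
#' @return Tibble `time_min`, `secreted_nmol`.
#' @export
secreted_amount <- function(trajectory) {
  total <- attr(trajectory, "total_amount_nmol")
  if (is.null(total)) {
    rlang::abort("secreted amount requires an amount-conserving trajectory",
                 class = "serovolt_config_error")
  }
  tibble::tibble(time_min = trajectory$time_min,
                 secreted_nmol = total[1] - total)
}
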