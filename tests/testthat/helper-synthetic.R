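# shared fixtures: everything is generated in code, nothing read from disk

control_params <- function(...) mm_params(...)

# freeze everything except the named parameters
freeze_except <- function(free) {
  setdiff(serovolt:::FITTABLE_MM_PARAMS, free)
}

# deSolve reference solution of the release/clearance ODE on a given grid
mm_reference_solution <- function(params, times, stim_start = 5,
                                  stim_end = 7) {
  deriv <- function(t, y, parms) {
    r <- serovolt:::release_envelope(t, params, stim_start, stim_end)
    list(r - uptake_rate(max(y[1], 0), params))
  }
  y0 <- if (is.null(params$C0)) mm_steady_state(params$R_basal, params) else params$C0
  out <- deSolve::lsoda(c(C = y0), times, deriv, NULL,
                        rtol = 1e-10, atol = 1e-10)
  as.numeric(out[, "C"])
}

# deSolve reference for the amount-conserving four-compartment system
fcm_reference_solution <- function(params, times) {
  c0 <- dose_to_initial_peritoneal_concentration(params)
  vols_L <- params$volumes_mL / 1000
  y0 <- c(c0 * vols_L[[1]], 0, 0, 0)
  deriv <- function(t, y, parms) {
    list(serovolt:::fcm_deriv(y, params, "amount", "repaired"))
  }
  out <- deSolve::lsoda(y0, times, deriv, NULL, rtol = 1e-10, atol = 1e-10)
  sweep(out[, -1, drop = FALSE], 2, as.numeric(vols_L), "/")
}

default_shape <- function(...) cv_shape_spec(...)
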