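# Parameters the RMSE fitter may vary. alpha/beta are always fixed: they are
# pure multipliers of V_max1/V_max2 and hence non-identifiable jointly.
FITTABLE_MM_PARAMS <- c("R_max", "tau_on", "tau_off",
                        "V_max1", "K_m1", "V_max2", "K_m2")

#' Fit the dual-uptake model to an evoked trace by RMSE gradient descent
#'
#' Minimises the root-mean-square error between an explicit-Euler forward
#' simulation and the observed trace over the free kinetic parameters.
#' Optimisation runs in log-parameter space (positivity by construction)
#' with forward-difference gradients and a backtracking line search, stopping
#' when the relative RMSE improvement falls below `tol` or after `max_iter`
#' iterations. A seeded multi-start (jittered copies of `init`, best final
#' RMSE wins) replaces the interactive step of semi-automatic fitting.
#'
#' @param trace A [concentration_trace()] covering the stimulation window
#'   (annotated on the trace or supplied via `protocol` + its onset in the
#'   trace metadata).
#' @param protocol The [stim_protocol()] used to evoke the trace.
#' @param init Initial [mm_params()].
#' @param frozen Character vector of parameter names held at their `init`
#'   values. Anything outside the fittable set (R_max, tau_on, tau_off,
#'   V_max1, K_m1, V_max2, K_m2) is always fixed. Freezing everything is a
#'   configuration error.
#' @param n_starts Number of multi-start inits (the first is `init` itself).
#' @param jitter_sd Log-normal jitter SD for the extra starts.
#' @param dt Euler step used inside the cost function, s.
#' @param tol Relative RMSE improvement threshold for convergence.
#' @param max_iter Iteration cap per start.
#' @param seed Integer seed for the jittered starts.
#' @return An `mm_fit` object: `fitted` (an `mm_params`), `rmse`, `iterations`,
#'   `converged`, `frozen`, `free`, plus the trace and settings. Use
#'   [param_ratios()] to compare against a control fit, and `tidy()` /
#'   `glance()` for tabular summaries.
#' @export
mm_fit <- function(trace, protocol = stim_protocol(), init = mm_params(),
                   frozen = c("tau_on", "tau_off"),
                   n_starts = 5, jitter_sd = 0.15,
                   dt = 0.01, tol = 1e-6, max_iter = 2000, seed = 1L) {
  stopifnot(inherits(trace, "concentration_trace"), inherits(init, "mm_params"))
  free <- setdiff(FITTABLE_MM_PARAMS, frozen)
  if (length(free) == 0) {
    rlang::abort("all parameters frozen: nothing to fit",
                 class = "serovolt_config_error")
  }
  sw <- stim_window(trace)
  if (any(is.na(sw))) {
    rlang::abort("trace must carry a stimulation window annotation",
                 class = "serovolt_validation_error")
  }
  duration <- trace$time_s[nrow(trace)] - trace$time_s[1]
  fs <- 1 / trace_dt(trace)
  obs <- trace$concentration_nM
  cost <- function(theta) {
    p <- init
    p[free] <- as.list(exp(theta))
    p <- structure(p, class = "mm_params")
    sim <- mm_simulate(p, protocol, dt = dt, duration = duration,
                       stim_start_s = sw[1], resample_hz = fs)
    r <- sim$concentration_nM[seq_along(obs)] - obs
    sqrt(mean(r^2))
  }
  theta0 <- log(pmax(unlist(init[free]), 1e-9))
  starts <- list(theta0)
  if (n_starts > 1) {
    jit <- withr::with_seed(seed, replicate(n_starts - 1,
      theta0 + stats::rnorm(length(theta0), 0, jitter_sd), simplify = FALSE))
    starts <- c(starts, jit)
  }
  runs <- purrr::map(starts, function(th) descend(cost, th, tol, max_iter))
  best <- runs[[which.min(purrr::map_dbl(runs, "value"))]]
  fitted <- init
  fitted[free] <- as.list(exp(best$par))
  fitted <- structure(fitted, class = "mm_params")
  structure(list(fitted = fitted, rmse = best$value,
                 iterations = best$iterations, converged = best$converged,
                 frozen = intersect(frozen, FITTABLE_MM_PARAMS), free = free,
                 init = init, trace = trace, protocol = protocol,
                 n_starts = n_starts, dt = dt, seed = seed),
            class = "mm_fit")
}

# log-space gradient descent with backtracking line search
descend <- function(cost, theta, tol, max_iter) {
  f <- cost(theta)
  if (!is.finite(f)) {
    return(list(par = theta, value = Inf, iterations = 0L, converged = FALSE))
  }
  step <- 0.1
  h <- 1e-6
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    g <- vapply(seq_along(theta), function(j) {
      tp <- theta
      tp[j] <- tp[j] + h
      (cost(tp) - f) / h
    }, numeric(1))
    gn <- sqrt(sum(g^2))
    if (!is.finite(gn) || gn < 1e-12) {
      converged <- TRUE
      break
    }
    dir <- -g / gn
    accepted <- FALSE
    s <- step
    for (bt in 1:25) {
      f_new <- cost(theta + s * dir)
      if (is.finite(f_new) && f_new < f) {
        accepted <- TRUE
        break
      }
      s <- s / 2
    }
    if (!accepted) {
      converged <- TRUE  # no descent direction at line-search resolution
      break
    }
    rel <- (f - f_new) / max(f, 1e-12)
    theta <- theta + s * dir
    f <- f_new
    step <- min(s * 2, 1)
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  list(par = theta, value = f, iterations = iter, converged = converged)
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> RMSE %.4g nM after %d iterations (%s)\n",
              x$rmse, x$iterations,
              if (x$converged) "converged" else "not converged"))
  cat("  free:  ", paste(x$free, collapse = ", "), "\n")
  if (length(x$frozen)) cat("  frozen:", paste(x$frozen, collapse = ", "), "\n")
  for (p in x$free) cat(sprintf("    %-7s %.5g\n", p, x$fitted[[p]]))
  invisible(x)
}

#' Post/control parameter ratios between two fits
#'
#' Elementwise `fitted_post / fitted_control` for the free parameters (the
#' drug-induced fold change of each kinetic constant); frozen parameters
#' report ratio 1. Both fits must share the same frozen set.
#'
#' @param post,control `mm_fit` objects.
#' @return A tibble with columns `term`, `post`, `control`, `ratio`.
#' @export
param_ratios <- function(post, control) {
  stopifnot(inherits(post, "mm_fit"), inherits(control, "mm_fit"))
  if (!setequal(post$frozen, control$frozen)) {
    rlang::abort("post and control fits must share the same frozen set",
                 class = "serovolt_config_error")
  }
  terms <- FITTABLE_MM_PARAMS
  purrr::map_dfr(terms, function(p) {
    pv <- post$fitted[[p]]
    cv <- control$fitted[[p]]
    ratio <- if (p %in% post$frozen) 1 else {
      if (cv == 0) {
        rlang::abort(sprintf("control %s is zero: ratio undefined", p),
                     class = "serovolt_undefined_ratio_error")
      }
      pv / cv
    }
    tibble::tibble(term = p, post = pv, control = cv, ratio = ratio)
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a dual-uptake model fit
#'
#' @param x An `mm_fit`.
#' @param ... Unused.
#' @return One row per fittable parameter: `term`, `estimate`, `init`,
#'   `frozen`.
#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  purrr::map_dfr(FITTABLE_MM_PARAMS, function(p) {
    tibble::tibble(term = p, estimate = x$fitted[[p]], init = x$init[[p]],
                   frozen = p %in% x$frozen)
  })
}

#' @rdname tidy.mm_fit
#' @return `glance()`: a one-row tibble with `rmse`, `iterations`,
#'   `converged`, `n_free`, `n_starts`.
#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, iterations = x$iterations,
                 converged = x$converged, n_free = length(x$free),
                 n_starts = x$n_starts)
}
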