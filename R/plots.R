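#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an evoked concentration trace
#'
#' Concentration against time with the stimulation window shaded.
#'
#' @param object A [concentration_trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot concentration_trace
#' @export
autoplot.concentration_trace <- function(object, ...) {
  sw <- stim_window(object)
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$time_s, .data$concentration_nM))
  if (!any(is.na(sw))) {
    p <- p + ggplot2::annotate("rect", xmin = sw[1], xmax = sw[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "red")
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "serotonin (nM)") +
    ggplot2::theme_minimal()
}

#' Plot a basal serotonin series
#'
#' @param object An [fscav_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fscav_series
#' @export
autoplot.fscav_series <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$time_min, .data$concentration_nM)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "ambient serotonin (nM)") +
    ggplot2::theme_minimal()
}

#' Plot a four-compartment trajectory
#'
#' All four compartment concentration curves on a common time axis.
#'
#' @param object An [fcm_simulate()] trajectory.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fcm_trajectory
#' @export
autoplot.fcm_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time_min",
                              names_to = "compartment", values_to = "nM")
  long$compartment <- sub("^C_(.*)_nM$", "\\1", long$compartment)
  ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$nM,
                                     colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "escitalopram (nM)") +
    ggplot2::theme_minimal()
}

#' Plot a power spectral density
#'
#' Normalised power against frequency, with the power-weighted mean
#' frequency marked.
#'
#' @param object A [welch_psd()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot psd_result
#' @export
autoplot.psd_result <- function(object, ...) {
  wf <- weighted_frequency(object)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$frequency_hz, .data$normalized_power)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = wf, linetype = "dashed") +
    ggplot2::labs(x = "frequency (Hz)", y = "normalised power") +
    ggplot2::theme_minimal()
}

#' Plot the uptake-inhibition scenario traces
#'
#' @param scenarios An [mm_scenarios()] tibble.
#' @return A ggplot overlaying control and the three perturbed simulations.
#' @export
plot_scenarios <- function(scenarios) {
  ggplot2::ggplot(scenarios,
                  ggplot2::aes(.data$time_s, .data$concentration_nM,
                               colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(control = "black",
                                            km2_x10 = "#3366cc",
                                            km1_x10 = "#ff8800",
                                            `km1_x10_vmax1_x0.5` = "#cc2222")) +
    ggplot2::labs(x = "time (s)", y = "serotonin (nM)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
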