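#' Electrical stimulation protocol
#'
#' Describes the biphasic pulse train used to evoke serotonin release from
#' the medial forebrain bundle. The in vivo default mirrors the standard
#' protocol: 60 Hz, 360 uA biphasic pulses of 2 ms width for 2 s
#' (120 pulses).
#'
#' @param frequency_hz Pulse frequency in Hz (> 0).
#' @param duration_s Total train duration in seconds (>= 0).
#' @param pulse_amplitude_uA Pulse amplitude in microamps.
#' @param pulse_width_ms Single-pulse width in milliseconds.
#' @param biphasic Logical, biphasic pulses.
#' @return A `stim_protocol` object.
#' @export
#' @examples
#' pulse_count(stim_protocol())            # 120
#' pulse_count(stim_protocol(duration_s = 1))  # 60
stim_protocol <- function(frequency_hz = 60, duration_s = 2,
                          pulse_amplitude_uA = 360, pulse_width_ms = 2,
                          biphasic = TRUE) {
  if (!is.finite(frequency_hz) || frequency_hz <= 0) {
    rlang::abort("frequency_hz must be positive",
                 class = "serovolt_validation_error")
  }
  if (!is.finite(duration_s) || duration_s < 0) {
    rlang::abort("duration_s must be non-negative",
                 class = "serovolt_validation_error")
  }
  structure(list(frequency_hz = frequency_hz, duration_s = duration_s,
                 pulse_amplitude_uA = pulse_amplitude_uA,
                 pulse_width_ms = pulse_width_ms, biphasic = biphasic),
            class = "stim_protocol")
}

#' Number of pulses delivered by a stimulation train
#'
#' @param protocol A [stim_protocol()].
#' @return Integer pulse count, `round(frequency * duration)`.
#' @export
pulse_count <- function(protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  as.integer(round(protocol$frequency_hz * protocol$duration_s))
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol> %g Hz x %g s (%d pulses), %g uA, %g ms%s\n",
              x$frequency_hz, x$duration_s, pulse_count(x),
              x$pulse_amplitude_uA, x$pulse_width_ms,
              if (x$biphasic) ", biphasic" else ""))
  invisible(x)
}
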