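#' Speed of light in vacuum (m/s)
#'
#' Exact SI value, used throughout the range and phase conversions.
#' @keywords internal
SPEED_OF_LIGHT <- 299792458

#' FMCW radar configuration
#'
#' Bundles the chirp and framing parameters of a frequency-modulated
#' continuous-wave (FMCW) radar. The defaults describe a 60--63 GHz device
#' sweeping 3 GHz per 33 microsecond chirp at a 20 Hz frame rate, which gives
#' a range-bin (spherical shell) depth of about 5 cm.
#'
#' @param f_min Carrier start frequency in Hz. The chirp sweeps upward from
#'   this frequency.
#' @param bandwidth Swept bandwidth \eqn{B} in Hz; sets the range-bin depth
#'   \eqn{c/(2B)}.
#' @param chirp_duration Duration of one chirp in seconds; together with
#'   `bandwidth` it determines the default frequency slope.
#' @param slope Frequency-increase rate \eqn{S} in Hz/s.
#' @param frame_rate Frame (slow-time sampling) rate in Hz.
#' @param min_range,max_range Spatial gate in metres. Bins closer than
#'   `min_range` are contaminated by antenna cross-talk; bins beyond
#'   `max_range` lie outside the bed.
#'
#' @return An object of class `radar_config`: a named list with the above
#'   fields plus `frame_period` (s) and `c` (speed of light, m/s).
#' @examples
#' cfg <- radar_config()
#' shell_depth(cfg) # ~0.05 m
#' @export
radar_config <- function(f_min = 60e9,
                         bandwidth = 3e9,
                         chirp_duration = 33e-6,
                         slope = bandwidth / chirp_duration,
                         frame_rate = 20,
                         min_range = 0.45,
                         max_range = 3.0) {
  stopifnot(
    f_min > 0, bandwidth > 0, slope > 0, frame_rate > 0,
    min_range > 0, min_range < max_range
  )
  structure(
    list(
      f_min = f_min,
      bandwidth = bandwidth,
      chirp_duration = chirp_duration,
      slope = slope,
      frame_rate = frame_rate,
      frame_period = 1 / frame_rate,
      min_range = min_range,
      max_range = max_range,
      c = SPEED_OF_LIGHT
    ),
    class = "radar_config"
  )
}

#' @export
print.radar_config <- function(x, ...) {
  cat("<radar_config>\n")
  cat(sprintf("  sweep: %.1f-%.1f GHz (B = %.2f GHz, S = %.3g Hz/s)\n",
              x$f_min / 1e9, (x$f_min + x$bandwidth) / 1e9,
              x$bandwidth / 1e9, x$slope))
  cat(sprintf("  frame rate: %g Hz (Nyquist %g Hz)\n",
              x$frame_rate, nyquist_limit(x)))
  cat(sprintf("  shell depth: %.3f m, spatial gate [%.2f, %.2f] m\n",
              shell_depth(x), x$min_range, x$max_range))
  invisible(x)
}

#' Range of a static reflector from its beat frequency
#'
#' An FMCW radar ranges a target from the beat frequency \eqn{f_d} between
#' transmitted and received chirps: \eqn{d = f_d c / (2S)} with \eqn{S} the
#' chirp slope.
#'
#' @param f_d Beat frequency in Hz (non-negative; vectorised).
#' @param config A [radar_config()].
#' @return Range(s) in metres.
#' @examples
#' beat_frequency_to_range(606.1e3, radar_config()) # ~1 m
#' @export
beat_frequency_to_range <- function(f_d, config = radar_config()) {
  if (any(f_d < 0)) {
    stop("beat frequency must be non-negative", call. = FALSE)
  }
  f_d * config$c / (2 * config$slope)
}

#' Depth of one range bin (spherical shell)
#'
#' The frequency resolution of the chirp spectrum partitions space into
#' shells of depth \eqn{c/(2B)}; a 3 GHz sweep gives about 5 cm.
#'
#' @inheritParams beat_frequency_to_range
#' @return Shell depth in metres.
#' @export
shell_depth <- function(config = radar_config()) {
  if (config$bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
  config$c / (2 * config$bandwidth)
}

#' Convert a displacement to radar phase
#'
#' Within one range bin, a target displacement \eqn{R} maps linearly to the
#' phase of the reflected wave: \eqn{\phi = 4\pi f_{min} R / c}. Positive
#' phase change corresponds to the target moving away from the radar.
#'
#' @param displacement Displacement(s) in metres.
#' @inheritParams beat_frequency_to_range
#' @return Phase in radians.
#' @export
displacement_to_phase <- function(displacement, config = radar_config()) {
  4 * pi * config$f_min * displacement / config$c
}

#' Convert radar phase to displacement
#'
#' Exact inverse of [displacement_to_phase()].
#'
#' @param phase Phase in radians (unwrapped).
#' @inheritParams beat_frequency_to_range
#' @return Displacement in metres.
#' @export
phase_to_displacement <- function(phase, config = radar_config()) {
  config$c * phase / (4 * pi * config$f_min)
}

#' Nyquist limit of the frame rate
#'
#' The frame rate samples the slow-time (vital-sign) motion; its Nyquist
#' limit must exceed the highest heart frequency of interest. At 20 Hz the
#' limit is 10 Hz, well above the 3.66 Hz maximum heart rate.
#'
#' @inheritParams beat_frequency_to_range
#' @return Frequency in Hz.
#' @export
nyquist_limit <- function(config = radar_config()) {
  config$frame_rate / 2
}

#' Rate resolution of an analysis window
#'
#' A window of length `window_s` seconds resolves frequency to
#' `1/window_s` Hz, i.e. `60/window_s` events per minute. The default 60 s
#' window distinguishes rates down to 1 BPM.
#'
#' @param window_s Window length in seconds.
#' @return Resolution in breaths/beats per minute.
#' @export
rate_resolution_bpm <- function(window_s = 60) {
  stopifnot(window_s > 0)
  60 / window_s
}
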