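# Reference vital rates from PSG-like contact channels: ECG heart rate via
# a stationary wavelet transform (Symlet 4) and belt breathing rate via the
# same autocorrelation algorithm used for the radar bins.

# Symlet-4 analysis filters (orthonormal, 8 taps). These are the standard
# published coefficients; the sym4 shape resembles the QRS complex, which is
# why its detail bands concentrate QRS energy.
SYM4_DEC_LO <- c(-0.07576571478927333, -0.02963552764599851,
                 0.49761866763201545, 0.80373875180591614,
                 0.29785779560527736, -0.09921954357684722,
                 -0.01260396726203783, 0.03222310060404270)
SYM4_DEC_HI <- c(-0.03222310060404270, -0.01260396726203783,
                 0.09921954357684722, 0.29785779560527736,
                 -0.80373875180591614, 0.49761866763201545,
                 0.02963552764599851, -0.07576571478927333)

#' Stationary wavelet detail coefficients (Symlet 4)
#'
#' Undecimated (a trous) wavelet decomposition with circular boundary
#' handling: at level j the analysis filters are upsampled by `2^(j-1)`, so
#' every level keeps the input length and stays time-aligned with it. Detail
#' level j spans roughly `fs/2^(j+1)` to `fs/2^j` Hz; at 256 Hz, levels 4
#' and 5 cover about 8--16 and 4--8 Hz, where QRS energy concentrates.
#'
#' @param x Numeric signal.
#' @param n_levels Decomposition depth.
#' @return Matrix `length(x)` x `n_levels` of detail coefficients (column j
#'   = level j).
#' @export
swt_details <- function(x, n_levels = 5) {
  n <- length(x)
  stopifnot(n > length(SYM4_DEC_LO) * 2^(n_levels - 1))
  circ_filter <- function(a, h, m) {
    out <- numeric(n)
    base <- seq_len(n) - 1
    for (i in seq_along(h)) {
      idx <- ((base + (i - 1) * m) %% n) + 1
      out <- out + h[i] * a[idx]
    }
    out
  }
  details <- matrix(0, n, n_levels)
  approx_j <- x
  for (j in seq_len(n_levels)) {
    m <- 2^(j - 1)
    details[, j] <- circ_filter(approx_j, SYM4_DEC_HI, m)
    approx_j <- circ_filter(approx_j, SYM4_DEC_LO, m)
  }
  details
}

#' Heart rate from one ECG window
#'
#' The ECG is decomposed with the stationary wavelet transform (Symlet 4);
#' the detail levels covering the typical QRS band are summed, their Hilbert
#' envelope is computed and lightly smoothed, and envelope peaks mark the
#' QRS complexes. The heart rate is the inverse of the average peak-to-peak
#' interval. The window counts as not detected with fewer than 3 peaks or a
#' mean interval outside 40--180 BPM.
#'
#' @param x ECG samples of one analysis window.
#' @param fs Sampling rate in Hz (256 for the reference ECG).
#' @param levels Detail levels summed for QRS extraction.
#' @param hr_bounds_bpm Plausible heart-rate range in BPM.
#' @return One-row tibble: `detected`, `rate_bpm`, `quality_sd` (s),
#'   `fail_reason`.
#' @export
ecg_heart_rate <- function(x, fs = 256, levels = c(4, 5),
                           hr_bounds_bpm = c(40, 180)) {
  if (anyNA(x)) stop("ECG window contains NA", call. = FALSE)
  not_detected <- function(reason) {
    tibble::tibble(detected = FALSE, rate_bpm = NA_real_,
                   quality_sd = NA_real_, fail_reason = reason)
  }
  n_levels <- max(levels)
  det <- swt_details(x, n_levels)
  comp <- rowSums(det[, levels, drop = FALSE])
  env <- analytic_envelope(comp)
  k <- max(3L, round(0.04 * fs))
  env <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
  env[is.na(env)] <- 0
  if (max(env) < 1e-9) return(not_detected("flat_signal"))
  pk <- find_peaks(env, min_prominence = 0.35 * stats::quantile(env, 0.98),
                   min_distance = floor(60 / hr_bounds_bpm[2] * fs))
  if (length(pk) < 3) return(not_detected("too_few_peaks"))
  mean_int <- mean(diff((pk - 1) / fs))
  if (mean_int < 60 / hr_bounds_bpm[2] || mean_int > 60 / hr_bounds_bpm[1]) {
    return(not_detected("outside_physiological_range"))
  }
  tibble::tibble(
    detected = TRUE,
    rate_bpm = 60 / mean_int,
    quality_sd = stats::sd(diff((pk - 1) / fs)),
    fail_reason = "none"
  )
}

#' Breathing rate from one belt window
#'
#' The thorax belt signal is proportional to the same torso in/deflation the
#' radar observes, so the belt rate uses the identical autocorrelation
#' algorithm as the radar breathing path ([breathing_rate_from_signal()]),
#' just without bin selection.
#'
#' @param x Belt samples of one analysis window.
#' @param fs Sampling rate in Hz (32 for the reference belt).
#' @return One-row tibble as returned by [breathing_rate_from_signal()].
#' @export
belt_breathing_rate <- function(x, fs = 32) {
  breathing_rate_from_signal(x, fs)
}
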