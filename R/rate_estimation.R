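# Per-window breathing-rate (autocorrelation) and heart-rate (peak-interval)
# estimation from the selected candidate bins.

#' Autocorrelogram with lag-local normalisation
#'
#' Correlation of the signal with itself at each lag,
#' \eqn{\rho(k) = Cov(X_t, X_{t-k}) / (\sigma(X_t)\,\sigma(X_{t-k}))},
#' where the covariance and both standard deviations are computed over the
#' overlapping segments of each shift. Unlike the fixed-denominator sample
#' ACF, every lag is a genuine Pearson correlation, so \eqn{|\rho(k)| \le 1}
#' and \eqn{\rho(0) = 1}.
#'
#' @param x Windowed signal (numeric vector), non-constant.
#' @param fs Sampling rate in Hz.
#' @param max_lag_s Largest lag evaluated, in seconds.
#' @return An `autocorrelogram`: list with `rho` (length `k_max + 1`),
#'   `lag_s`, `fs`.
#' @export
autocorrelogram <- function(x, fs, max_lag_s = 30) {
  n <- length(x)
  stopifnot(n >= 2)
  if (stats::sd(x) == 0) stop("zero-variance window", call. = FALSE)
  k_max <- min(n - 3L, round(max_lag_s * fs))
  ks <- seq_len(k_max)
  m <- n - ks # overlap length at each lag
  # lagged product sums sum_i x[i+k] x[i] for all k at once via FFT
  np <- stats::nextn(2L * n)
  xf <- stats::fft(c(x, rep(0, np - n)))
  cc <- Re(stats::fft(xf * Conj(xf), inverse = TRUE)) / np
  s_ab <- cc[ks + 1]
  # segment sums via cumulative sums: a = x[(k+1):n], b = x[1:(n-k)]
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  sum_a <- cs[n] - cs[ks]
  sum_b <- cs[n - ks]
  sq_a <- cs2[n] - cs2[ks]
  sq_b <- cs2[n - ks]
  var_a <- (sq_a - sum_a^2 / m) / (m - 1)
  var_b <- (sq_b - sum_b^2 / m) / (m - 1)
  cov_ab <- (s_ab - sum_a * sum_b / m) / (m - 1)
  denom <- sqrt(pmax(var_a, 0) * pmax(var_b, 0))
  rho <- c(1, ifelse(denom > 0, cov_ab / denom, NA_real_))
  structure(list(rho = rho, lag_s = (0:k_max) / fs, fs = fs),
            class = "autocorrelogram")
}

#' Middle-peak width test of an autocorrelogram
#'
#' Random body motions broaden or collapse the autocorrelogram's central
#' peak. Its width is the lag distance between the troughs surrounding lag
#' 0; by symmetry this is twice the first trough lag on the positive side.
#' Rate computation proceeds only when the width lies inside the expected
#' vital cycle range (for breathing 2.5--10 s, from the 0.1--0.4 Hz band).
#' Bounds are applied inclusively with a one-lag pad, since trough lags are
#' quantised to the frame period.
#'
#' @param ac An [autocorrelogram()].
#' @param cycle_bounds Allowed width range in seconds.
#' @param trough_prominence Minimum prominence of a trough; small enough to
#'   find the troughs of a weak periodic signal, large enough to ignore
#'   noise ripples riding on an artifact-dominated correlogram.
#' @return `TRUE` (pass) or `FALSE` (no trough found, or width outside the
#'   bounds).
#' @export
middle_peak_width_test <- function(ac, cycle_bounds = c(2.5, 10),
                                   trough_prominence = 0.05) {
  trough <- find_peaks(-ac$rho, min_prominence = trough_prominence)
  if (!length(trough)) return(FALSE)
  width <- 2 * ac$lag_s[trough[1]]
  pad <- 1 / ac$fs
  width >= cycle_bounds[1] - pad && width <= cycle_bounds[2] + pad
}

#' Breathing rate of one windowed signal
#'
#' The windowed displacement (radar bin) or belt signal is autocorrelated
#' as-is and screened with the middle-peak width test: breathing dominates
#' the variance of a vital-sign bin, a broadband artifact collapses the
#' middle peak below the breathing cycle range, and a drift or body-movement
#' bump widens it beyond (bandpass filtering first would fold any artifact
#' into the breathing band and blunt exactly this test).
#' Peaks of the autocorrelogram are then detected; the rate is
#' the inverse of the first peak lag inside the physiological cycle range
#' (2.5--10 s), in BPM. Quality descriptors are the correlation at that
#' first peak and the standard deviation of the inter-peak lag distances
#' (over all detected peaks up to the 30 s lag horizon, so at least two peak
#' distances exist even for slow breathing).
#'
#' @param x Windowed signal (numeric vector).
#' @param fs Sampling rate in Hz.
#' @param filter Bandpass filter the input to the breathing band first
#'   (off by default; see above).
#' @param cycle_bounds Physiological breathing cycle range in seconds.
#' @param peak_prominence Minimum autocorrelation peak prominence.
#' @return One-row tibble: `detected`, `rate_bpm`, `quality_rho`,
#'   `quality_sd` (seconds), `fail_reason`.
#' @export
breathing_rate_from_signal <- function(x, fs, filter = FALSE,
                                       cycle_bounds = c(2.5, 10),
                                       peak_prominence = 0.1) {
  not_detected <- function(reason) {
    tibble::tibble(detected = FALSE, rate_bpm = NA_real_,
                   quality_rho = NA_real_, quality_sd = NA_real_,
                   fail_reason = reason)
  }
  if (stats::sd(x) == 0) return(not_detected("zero_variance"))
  if (filter) x <- bandpass(x, fs, vital_band("breathing"))
  if (stats::sd(x) == 0) return(not_detected("zero_variance"))
  ac <- autocorrelogram(x, fs, max_lag_s = 30)
  if (!middle_peak_width_test(ac, cycle_bounds)) {
    return(not_detected("width_test"))
  }
  peaks <- find_peaks(ac$rho, min_prominence = peak_prominence,
                      min_distance = max(2L, round(0.96 * cycle_bounds[1] * fs)))
  peaks <- peaks[ac$lag_s[peaks] > 1 / fs] # exclude the lag-0 peak region
  in_range <- peaks[ac$lag_s[peaks] >= cycle_bounds[1] &
                      ac$lag_s[peaks] <= cycle_bounds[2]]
  if (!length(in_range)) return(not_detected("no_peak_in_range"))
  first <- in_range[1]
  lag_first <- ac$lag_s[first]
  sd_ipd <- if (length(peaks) >= 3) stats::sd(diff(ac$lag_s[peaks])) else NA_real_
  tibble::tibble(
    detected = TRUE,
    rate_bpm = 60 / lag_first,
    quality_rho = ac$rho[first],
    quality_sd = sd_ipd,
    fail_reason = "none"
  )
}

#' Choose the best breathing estimate among candidate bins
#'
#' A smaller standard deviation of the inter-peak distances and a higher
#' first-peak correlation indicate a more consistent and clearer signal.
#' Candidates are ranked by first-peak correlation quantised to 0.02 steps,
#' with the inter-peak SD breaking ties (then proximity to the radar):
#' bandpass-filtered noise in an empty bin is quasi-periodic and can show
#' deceptively regular peak spacing, but never a high peak correlation, so
#' the correlation must dominate the ranking.
#'
#' @param fragments Tibble of per-bin results: columns of
#'   [breathing_rate_from_signal()] plus `bin_index`, `range_m`,
#'   `tpc_score`.
#' @return One-row tibble (the winning fragment), or a not-detected row if
#'   every candidate failed.
#' @export
choose_breathing_estimate <- function(fragments) {
  det <- fragments[fragments$detected, , drop = FALSE]
  if (nrow(det) == 0) {
    return(tibble::tibble(detected = FALSE, rate_bpm = NA_real_,
                          quality_rho = NA_real_, quality_sd = NA_real_,
                          fail_reason = "all_candidates_failed",
                          bin_index = NA_integer_, range_m = NA_real_,
                          tpc_score = NA_real_))
  }
  sd_rank <- ifelse(is.na(det$quality_sd), Inf, det$quality_sd)
  rho_rank <- round(det$quality_rho / 0.02)
  det[order(-rho_rank, sd_rank, det$bin_index), ][1, , drop = FALSE]
}

#' Heart rate from one normalised heart-band window
#'
#' Peaks of the envelope-normalised heart-band signal are detected with a
#' minimum prominence of 0.1 (normalised units) and a refractory separation
#' adapted to the signal's own periodicity: the candidate beat period is the
#' smallest autocorrelation-peak lag within the physiological range whose
#' correlation comes within 0.05 of the in-range maximum, and peaks closer
#' than 0.6 of that period are suppressed. The adaptive refractory window
#' matters near the low edge of the heart band, where the bandpass filter
#' attenuates the pulse fundamental while passing its second harmonic: fixed
#' band-based separation would then return double-rate intervals. The
#' peak-to-peak intervals are median filtered (kernel 3) to repair isolated
#' missed or spurious beats; the bin is discarded when the mean filtered
#' interval falls outside the physiological heart range. The rate is the
#' inverse of the mean filtered interval and the quality is the standard
#' deviation of the filtered intervals.
#'
#' @param nw A heartbeat-mode `normalized_window` (see [normalize_phase()]).
#' @param hr_bounds_bpm Physiological heart-rate range in BPM.
#' @param peak_prominence Minimum peak prominence (normalised units).
#' @return One-row tibble: `detected`, `rate_bpm`, `quality_sd` (s),
#'   `fail_reason`.
#' @export
heart_rate_from_bin <- function(nw, hr_bounds_bpm = c(48, 102),
                                peak_prominence = 0.1) {
  not_detected <- function(reason) {
    tibble::tibble(detected = FALSE, rate_bpm = NA_real_,
                   quality_sd = NA_real_, fail_reason = reason)
  }
  fs <- nw$fs
  period <- beat_period_hint(nw$p_hat, fs, hr_bounds_bpm)
  min_sep <- if (is.na(period)) {
    max(2L, floor(0.5 / nw$band[2] * fs))
  } else {
    max(2L, floor(0.6 * period * fs))
  }
  pk <- find_peaks(nw$p_hat, min_prominence = peak_prominence,
                   min_distance = min_sep)
  if (length(pk) < 3) return(not_detected("too_few_peaks"))
  # parabolic sub-sample interpolation of peak positions: at a 20 Hz frame
  # rate the raw 50 ms quantisation would bias the median-filtered intervals
  times <- peak_times(nw$p_hat, pk, fs)
  intervals <- diff(times)
  med <- stats::runmed(intervals, 3)
  mean_int <- mean(med)
  if (mean_int < 60 / hr_bounds_bpm[2] || mean_int > 60 / hr_bounds_bpm[1]) {
    return(not_detected("outside_physiological_range"))
  }
  tibble::tibble(
    detected = TRUE,
    rate_bpm = 60 / mean_int,
    quality_sd = stats::sd(med),
    fail_reason = "none"
  )
}

# Candidate beat period from the autocorrelation of the normalised signal:
# smallest in-range peak lag whose correlation is within `slack` of the
# in-range maximum. Both the pulse fundamental and its harmonics repeat at
# the true period, so the true lag always scores at the top; the smallest-lag
# preference keeps genuinely fast rates (whose doubled lag also fits the
# range) from being halved.
beat_period_hint <- function(p, fs, hr_bounds_bpm, slack = 0.05) {
  ac <- tryCatch(autocorrelogram(p, fs, max_lag_s = 60 / hr_bounds_bpm[1] * 1.1),
                 error = function(e) NULL)
  if (is.null(ac)) return(NA_real_)
  pk <- find_peaks(ac$rho, min_prominence = 0.05)
  lo <- 60 / hr_bounds_bpm[2] * 0.9
  hi <- 60 / hr_bounds_bpm[1] * 1.1
  in_range <- pk[ac$lag_s[pk] >= lo & ac$lag_s[pk] <= hi]
  if (!length(in_range)) return(NA_real_)
  best <- max(ac$rho[in_range])
  # a sub-range lag correlating as well means the signal repeats faster than
  # any physiological beat; the in-range lag is then only a multiple of that
  # faster period and must not set the refractory window
  sub <- pk[ac$lag_s[pk] < lo]
  if (length(sub) && max(ac$rho[sub]) >= best - slack) return(NA_real_)
  ac$lag_s[in_range[ac$rho[in_range] >= best - slack][1]]
}

#' Choose the best heart estimate among candidate bins
#'
#' The winning bin has the lowest standard deviation of the peak-to-peak
#' intervals; ties go to the higher TPC score.
#'
#' @param fragments Tibble of per-bin results from [heart_rate_from_bin()]
#'   plus `bin_index`, `range_m`, `tpc_score`.
#' @return One-row tibble, or a not-detected row if all bins were discarded.
#' @export
choose_heart_estimate <- function(fragments) {
  det <- fragments[fragments$detected, , drop = FALSE]
  if (nrow(det) == 0) {
    return(tibble::tibble(detected = FALSE, rate_bpm = NA_real_,
                          quality_sd = NA_real_,
                          fail_reason = "all_candidates_failed",
                          bin_index = NA_integer_, range_m = NA_real_,
                          tpc_score = NA_real_))
  }
  det[order(det$quality_sd, -det$tpc_score, det$bin_index), ][1, , drop = FALSE]
}
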