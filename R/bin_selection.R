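# Range-bin selection: spatial gating, artifact rejection, magnitude
# variability screening (breathing only) and temporal phase coherency
# scoring of the candidate bins.

#' Frequency bands of the two vital signs
#'
#' Breathing is searched in 0.1--0.4 Hz (6--24 BPM), the heartbeat pulse in
#' 0.8--1.7 Hz (48--102 BPM).
#' @param mode `"breathing"` or `"heartbeat"`.
#' @return Length-2 numeric band in Hz.
#' @export
vital_band <- function(mode = c("breathing", "heartbeat")) {
  mode <- match.arg(mode)
  if (mode == "breathing") c(0.1, 0.4) else c(0.8, 1.7)
}

#' Keep only range bins inside the informative spatial gate
#'
#' Bins closer than `min_range` are dominated by antenna cross-talk and bins
#' beyond `max_range` lie outside the bed, so only bins with centre range in
#' the closed interval \[`min_range`, `max_range`\] survive. Idempotent; if
#' nothing survives an empty (0-bin) signal is returned rather than an error.
#'
#' @param signal A `range_time_signal`.
#' @param config A [radar_config()] supplying the gate bounds.
#' @return The gated `range_time_signal` (bin order preserved) with an
#'   attribute `orig_bin` mapping rows back to the input bin indices.
#' @export
spatial_gate <- function(signal, config = radar_config()) {
  keep <- which(signal$bin_ranges >= config$min_range &
                  signal$bin_ranges <= config$max_range)
  prev <- attr(signal, "orig_bin") %||% seq_along(signal$bin_ranges)
  signal$displacement <- signal$displacement[keep, , drop = FALSE]
  signal$magnitude <- signal$magnitude[keep, , drop = FALSE]
  signal$bin_ranges <- signal$bin_ranges[keep]
  attr(signal, "orig_bin") <- prev[keep]
  signal
}

#' Slice one analysis window out of a recording
#'
#' @param signal A `range_time_signal`.
#' @param start_s Window start in seconds.
#' @param window_s Window length in seconds (default 60).
#' @return A `range_time_signal` restricted to the window frames.
#' @export
slice_window <- function(signal, start_s, window_s = 60) {
  fs <- signal$frame_rate
  i0 <- floor(start_s * fs) + 1L
  i1 <- i0 + round(window_s * fs) - 1L
  if (i1 > ncol(signal$displacement)) {
    stop("window [", start_s, ", ", start_s + window_s,
         "] s exceeds the recording", call. = FALSE)
  }
  signal$displacement <- signal$displacement[, i0:i1, drop = FALSE]
  signal$magnitude <- signal$magnitude[, i0:i1, drop = FALSE]
  signal$window_start <- start_s
  signal
}

#' Per-bin motion-artifact gate
#'
#' A range bin fails when its maximum absolute sample-to-sample displacement
#' difference exceeds the threshold (default 1 mm in 50 ms --- a change as
#' large as a whole breathing motion cannot be physiological between two
#' frames). The test runs separately per bin so that a moving limb does not
#' discard calm torso bins; if every bin fails, the whole window is marked
#' as having no radar vital signs.
#'
#' @param displacement Bins x samples displacement matrix (m).
#' @param threshold Maximum tolerated per-sample step in metres.
#' @return List with `pass` (logical per bin) and `all_failed` (flag).
#' @export
artifact_gate <- function(displacement, threshold = 1e-3) {
  stopifnot(ncol(displacement) >= 2)
  max_step <- apply(abs(displacement[, -1, drop = FALSE] -
                          displacement[, -ncol(displacement), drop = FALSE]),
                    1, max)
  pass <- max_step <= threshold
  list(pass = pass, all_failed = !any(pass))
}

#' Candidate bins by magnitude variability (breathing search only)
#'
#' A breathing human modulates the reflected energy, so the bins with the
#' highest temporal standard deviation of the magnitude signal localise the
#' body against static clutter. The `k_top` highest-SD bins are kept
#' together with `halo` neighbours on each side. Heartbeat search skips this
#' screen entirely: pulse-only bins do not stand out in magnitude.
#'
#' @param magnitude Bins x samples magnitude matrix.
#' @param k_top Number of top-SD seed bins.
#' @param halo Neighbour bins kept on each side of a seed.
#' @param eligible Optional logical/integer subset of bins allowed as seeds
#'   (e.g. artifact-gate survivors); the halo is clipped to eligible bins.
#' @return Sorted integer vector of candidate bin rows.
#' @export
magnitude_variability_candidates <- function(magnitude, k_top = 3, halo = 2,
                                             eligible = NULL) {
  n <- nrow(magnitude)
  if (is.null(eligible)) eligible <- seq_len(n)
  if (is.logical(eligible)) eligible <- which(eligible)
  if (!length(eligible)) return(integer(0))
  sds <- apply(magnitude[eligible, , drop = FALSE], 1, stats::sd)
  # ties broken towards the radar (lower bin index)
  seeds <- eligible[order(-sds, eligible)][seq_len(min(k_top, length(eligible)))]
  cand <- unique(sort(unlist(lapply(seeds, function(b) (b - halo):(b + halo)))))
  intersect(cand, eligible)
}

#' Bandpass, envelope-normalise and period-estimate one bin
#'
#' The displacement of one bin over one analysis window is bandpass filtered
#' with a zero-phase second-order Butterworth filter at the vital band, then
#' normalised by its Hilbert envelope, giving a signal bounded in (-1, 1).
#' The average period length is estimated from the zero crossings of the
#' normalised signal (twice the mean crossing-to-crossing interval).
#'
#' @param x Displacement samples of one bin (m).
#' @param fs Sampling (frame) rate in Hz.
#' @param mode `"breathing"` or `"heartbeat"` (sets the band).
#' @param env_floor Envelope floor to avoid division blow-ups in dead bins.
#' @return A `normalized_window` list (`p_hat`, `period_T` in s, `sigma`,
#'   `band`, `fs`), or `NULL` when fewer than 4 zero crossings are found
#'   (no periodicity at this bin).
#' @export
normalize_phase <- function(x, fs, mode = c("breathing", "heartbeat"),
                            env_floor = 1e-9) {
  mode <- match.arg(mode)
  if (stats::sd(x) == 0) return(NULL) # constant bin: no periodicity
  band <- vital_band(mode)
  filt <- bandpass(x, fs, band)
  if (stats::sd(filt) < 1e-14) return(NULL)
  env <- pmax(analytic_envelope(filt), env_floor)
  p_hat <- filt / env
  sgn <- sign(p_hat)
  sgn[sgn == 0] <- 1
  cross <- which(sgn[-1] != sgn[-length(sgn)])
  if (length(cross) < 4) return(NULL)
  # linear interpolation of crossing times for sub-sample period accuracy
  tc <- (cross - 1 + p_hat[cross] / (p_hat[cross] - p_hat[cross + 1])) / fs
  period_T <- 2 * mean(diff(tc))
  if (!is.finite(period_T) || period_T <= 0) return(NULL)
  structure(
    list(p_hat = p_hat, period_T = period_T, sigma = stats::sd(p_hat),
         band = band, mode = mode, fs = fs),
    class = "normalized_window"
  )
}

#' Temporal phase coherency of a normalised window
#'
#' Correlation of the envelope-normalised signal with itself shifted by its
#' estimated average period: high values indicate regular periodic motion at
#' that bin. The lag-aligned segments each have length `t0 - T`; the product
#' sum is divided by the segment standard deviations and the overlap sample
#' count, so scores are comparable across bins with different periods and
#' lie in \[-1, 1\] (up to the segment-mean contribution).
#'
#' @param nw A `normalized_window` from [normalize_phase()].
#' @param period_T Optional period override in seconds (defaults to the
#'   window's own estimate).
#' @return TPC score, or `NA` when a segment is constant (zero sigma) or the
#'   shift does not fit in the window.
#' @export
temporal_phase_coherency <- function(nw, period_T = NULL) {
  p <- nw$p_hat
  n <- length(p)
  T_samp <- round((period_T %||% nw$period_T) * nw$fs)
  if (T_samp < 1 || T_samp >= n - 1) return(NA_real_)
  a <- p[(T_samp + 1):n]
  b <- p[1:(n - T_samp)]
  sa <- stats::sd(a)
  sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(NA_real_)
  sum(a * b) / (sa * sb) / (length(a) - 1)
}

#' Select candidate range bins for one analysis window
#'
#' Composition of the bin-selection stages on one (spatially gated) window:
#' the per-bin artifact gate; for breathing additionally the magnitude
#' variability screen; then TPC scoring of the surviving bins, keeping the
#' five highest scores (ties towards nearer bins). An empty candidate set
#' carries the reason: `"all_bins_artifact"` when every bin failed the
#' motion gate (the window has no radar vital signs) or `"no_periodicity"`
#' when no bin produced a usable normalised signal.
#'
#' @param window A `range_time_signal` restricted to one window (see
#'   [slice_window()]), already spatially gated.
#' @param mode `"breathing"` or `"heartbeat"`.
#' @param k_top,halo Magnitude-screen parameters (breathing only).
#' @param artifact_threshold Per-sample step limit in metres.
#' @param n_keep Number of candidate bins retained.
#' @return A `candidate_set`: list with `bins` (tibble of `bin_index`,
#'   `row` in the gated matrix, `range_m`, `tpc_score`, descending),
#'   `normalized` (named list of
#'   `normalized_window`s keyed by bin index), `mode`, `window_start`,
#'   `empty_reason` (`"none"` if candidates exist).
#' @export
select_bins <- function(window, mode = c("breathing", "heartbeat"),
                        k_top = 3, halo = 2, artifact_threshold = 1e-3,
                        n_keep = 5) {
  mode <- match.arg(mode)
  empty <- function(reason) {
    structure(list(
      bins = tibble::tibble(bin_index = integer(0), range_m = numeric(0),
                            tpc_score = numeric(0)),
      normalized = list(), mode = mode,
      window_start = window$window_start %||% 0,
      empty_reason = reason
    ), class = "candidate_set")
  }
  if (nrow(window$displacement) == 0) return(empty("all_bins_artifact"))
  gate <- artifact_gate(window$displacement, artifact_threshold)
  if (gate$all_failed) return(empty("all_bins_artifact"))
  pool <- which(gate$pass)
  if (mode == "breathing") {
    pool <- magnitude_variability_candidates(window$magnitude, k_top, halo,
                                             eligible = pool)
  }
  fs <- window$frame_rate
  scores <- rep(NA_real_, length(pool))
  norms <- vector("list", length(pool))
  for (i in seq_along(pool)) {
    nw <- normalize_phase(window$displacement[pool[i], ], fs, mode)
    if (is.null(nw)) next
    norms[[i]] <- nw
    scores[i] <- temporal_phase_coherency(nw)
  }
  ok <- which(is.finite(scores))
  if (!length(ok)) return(empty("no_periodicity"))
  ord <- ok[order(-scores[ok], pool[ok])]
  keep <- ord[seq_len(min(n_keep, length(ord)))]
  orig <- attr(window, "orig_bin") %||% seq_along(window$bin_ranges)
  res <- structure(list(
    bins = tibble::tibble(
      bin_index = orig[pool[keep]],
      row = pool[keep], # row in the gated window matrix
      range_m = window$bin_ranges[pool[keep]],
      tpc_score = scores[keep]
    ),
    normalized = stats::setNames(norms[keep], orig[pool[keep]]),
    mode = mode,
    window_start = window$window_start %||% 0,
    empty_reason = "none"
  ), class = "candidate_set")
  res
}
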