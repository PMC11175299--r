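# Sliding analysis grid, radar-vs-reference pairing and agreement metrics.

#' Start times of the sliding analysis windows
#'
#' Windows of `window_s` seconds with `overlap_s` seconds of overlap (hop =
#' length - overlap, 20 s by default) covering the recording: starts at 0,
#' 20, 40, ... while `start + window_s <= duration`.
#'
#' @param duration Recording duration in seconds.
#' @param window_s Window length in seconds.
#' @param overlap_s Overlap between consecutive windows in seconds.
#' @return Numeric vector of start times (possibly empty).
#' @export
make_windows <- function(duration, window_s = 60, overlap_s = 40) {
  stopifnot(duration >= 0)
  if (overlap_s >= window_s) {
    stop("overlap must be smaller than the window length", call. = FALSE)
  }
  hop <- window_s - overlap_s
  if (duration < window_s) return(numeric(0))
  seq(0, duration - window_s, by = hop)
}

#' Joint radar/reference windows
#'
#' Windows in which both the radar and the reference algorithm found the
#' vital sign (subject presence is not controlled, so agreement is judged
#' only where both sensors report a rate).
#'
#' @param radar,reference Estimate tibbles on the same window grid (see
#'   [extract_vitals()]).
#' @return Tibble of joint windows: `window_start_s`, `rate_radar_bpm`,
#'   `rate_ref_bpm`.
#' @export
pair_windows <- function(radar, reference) {
  if (nrow(radar) != nrow(reference) ||
      !isTRUE(all.equal(sort(radar$window_start_s),
                        sort(reference$window_start_s)))) {
    stop("radar and reference estimates are on different window grids",
         call. = FALSE)
  }
  joined <- dplyr::inner_join(
    dplyr::select(radar, "window_start_s",
                  rate_radar_bpm = "rate_bpm", det_r = "detected"),
    dplyr::select(reference, "window_start_s",
                  rate_ref_bpm = "rate_bpm", det_p = "detected"),
    by = "window_start_s"
  )
  out <- dplyr::filter(joined, .data$det_r & .data$det_p)
  dplyr::select(out, "window_start_s", "rate_radar_bpm", "rate_ref_bpm")
}

#' Agreement metrics between radar and reference rate series
#'
#' Computes, per sensor pair: the detection rates (percentage of windows
#' with a rate), the joint detection rate, the proportion of joint windows
#' whose absolute rate difference is within each tolerance (inclusive
#' comparison), and the mean absolute percent error
#' MAPE = 100 * mean(|radar - ref| / ref) with the reference in the
#' denominator. With no joint windows the agreement metrics are reported as
#' `NA`, not zero.
#'
#' @inheritParams pair_windows
#' @param tolerances_bpm Tolerance levels k in BPM (defaults 1 and 3,
#'   the breathing levels; use `c(1, 5)` for heartbeat).
#' @param label Optional label (e.g. the radar position) carried in the
#'   report.
#' @return An `agreement_report` object; see [tidy.agreement_report()] and
#'   [glance.agreement_report()].
#' @export
agreement_metrics <- function(radar, reference, tolerances_bpm = c(1, 3),
                              label = NULL) {
  joint <- pair_windows(radar, reference)
  n <- nrow(radar)
  n_joint <- nrow(joint)
  diffs <- abs(joint$rate_radar_bpm - joint$rate_ref_bpm)
  tol <- tibble::tibble(
    tolerance_bpm = sort(tolerances_bpm),
    pct_within = if (n_joint > 0) {
      vapply(sort(tolerances_bpm), function(k) 100 * mean(diffs <= k),
             numeric(1))
    } else rep(NA_real_, length(tolerances_bpm))
  )
  structure(
    list(
      label = label %||% NA_character_,
      n_windows = n,
      n_joint = n_joint,
      detection_rate_radar = if (n > 0) 100 * mean(radar$detected) else NA_real_,
      detection_rate_reference = if (n > 0) 100 * mean(reference$detected) else NA_real_,
      joint_detection_rate = if (n > 0) 100 * n_joint / n else NA_real_,
      tolerance = tol,
      mape = if (n_joint > 0) {
        100 * mean(diffs / joint$rate_ref_bpm)
      } else NA_real_
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>",
      if (!is.na(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  cat(sprintf("  windows: %d (joint detections: %d)\n", x$n_windows, x$n_joint))
  cat(sprintf("  detection rate: radar %.1f%%, reference %.1f%%, joint %.1f%%\n",
              x$detection_rate_radar, x$detection_rate_reference,
              x$joint_detection_rate))
  for (i in seq_len(nrow(x$tolerance))) {
    cat(sprintf("  within +/-%g BPM: %.1f%%\n",
                x$tolerance$tolerance_bpm[i], x$tolerance$pct_within[i]))
  }
  cat(sprintf("  MAPE: %.2f%%\n", x$mape))
  invisible(x)
}

#' Tidy an agreement report into a long metric table
#'
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return Tibble with columns `label`, `metric`, `value`.
#' @method tidy agreement_report
#' @export
tidy.agreement_report <- function(x, ...) {
  tibble::tibble(
    label = x$label,
    metric = c("detection_rate_radar", "detection_rate_reference",
               "joint_detection_rate",
               paste0("pct_within_", x$tolerance$tolerance_bpm, "_bpm"),
               "mape"),
    value = c(x$detection_rate_radar, x$detection_rate_reference,
              x$joint_detection_rate, x$tolerance$pct_within, x$mape)
  )
}

#' One-row summary of an agreement report
#'
#' @inheritParams tidy.agreement_report
#' @return One-row tibble with the detection rates, tolerance proportions
#'   (`pct_within_<k>_bpm`), MAPE and window counts.
#' @method glance agreement_report
#' @export
glance.agreement_report <- function(x, ...) {
  wide <- stats::setNames(as.list(x$tolerance$pct_within),
                          paste0("pct_within_", x$tolerance$tolerance_bpm, "_bpm"))
  tibble::as_tibble(c(
    list(label = x$label, n_windows = x$n_windows, n_joint = x$n_joint,
         detection_rate_radar = x$detection_rate_radar,
         detection_rate_reference = x$detection_rate_reference,
         joint_detection_rate = x$joint_detection_rate),
    wide,
    list(mape = x$mape)
  ))
}

#' Breathing-band power profile across range bins
#'
#' For one analysis window, the breathing-band (0.1--0.4 Hz) power of every
#' gated range bin, with the bin picked by the automatic breathing pipeline
#' flagged. With a lateral radar, thoracic versus abdominal breathing moves
#' this chosen bin along the body axis.
#'
#' @param signal A `range_time_signal`.
#' @param config A [radar_config()].
#' @param window_start Window start in seconds.
#' @param window_s Window length in seconds.
#' @return Tibble: `bin_index`, `range_m`, `band_power`, `chosen`.
#' @export
compute_breathing_range_profile <- function(signal, config = radar_config(),
                                            window_start = 0, window_s = 60) {
  gated <- spatial_gate(signal, config)
  win <- slice_window(gated, window_start, window_s)
  fs <- signal$frame_rate
  orig <- attr(win, "orig_bin") %||% seq_along(win$bin_ranges)
  power <- vapply(seq_len(nrow(win$displacement)), function(b) {
    x <- win$displacement[b, ]
    if (stats::sd(x) == 0) return(0)
    stats::var(bandpass(x, fs, vital_band("breathing")))
  }, numeric(1))
  cs <- select_bins(win, "breathing")
  chosen_bin <- NA_integer_
  if (cs$empty_reason == "none") {
    frags <- dplyr::bind_rows(lapply(seq_len(nrow(cs$bins)), function(i) {
      frag <- breathing_rate_from_signal(win$displacement[cs$bins$row[i], ], fs)
      frag$bin_index <- cs$bins$bin_index[i]
      frag$range_m <- cs$bins$range_m[i]
      frag$tpc_score <- cs$bins$tpc_score[i]
      frag
    }))
    choice <- choose_breathing_estimate(frags)
    if (choice$detected) chosen_bin <- choice$bin_index
  }
  tibble::tibble(
    bin_index = orig,
    range_m = win$bin_ranges,
    band_power = power,
    chosen = orig == chosen_bin & !is.na(chosen_bin)
  )
}
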