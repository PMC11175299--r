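# ggplot2 views of the main result types.

#' Plot a range-time signal as a displacement map
#'
#' @param object A `range_time_signal`.
#' @param what `"displacement"` (m) or `"magnitude"`.
#' @param ... Unused.
#' @return A ggplot object (range vs time, fill = signal).
#' @method autoplot range_time_signal
#' @export
autoplot.range_time_signal <- function(object, what = c("displacement", "magnitude"),
                                       ...) {
  what <- match.arg(what)
  m <- object[[what]]
  df <- tibble::tibble(
    range_m = rep(object$bin_ranges, times = ncol(m)),
    time_s = rep((seq_len(ncol(m)) - 1) / object$frame_rate,
                 each = length(object$bin_ranges)),
    value = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$range_m,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = what) +
    ggplot2::labs(x = "time (s)", y = "range (m)")
}

#' Plot a breathing range profile
#'
#' Bar chart of breathing-band power per range bin with the automatically
#' chosen bin highlighted, mirroring the thoracic/abdominal comparison view.
#'
#' @param profile Tibble from [compute_breathing_range_profile()].
#' @return A ggplot object.
#' @export
plot_range_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$range_m, .data$band_power,
                                        fill = .data$chosen)) +
    ggplot2::geom_col(width = 0.04) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                               guide = "none") +
    ggplot2::labs(x = "range (m)", y = "breathing-band power (m²)")
}

#' Plot per-window rate estimates against a reference
#'
#' @param estimates Estimate tibble (see [extract_vitals()]).
#' @param reference Optional second estimate tibble (e.g. belt/ECG) drawn as
#'   a line.
#' @return A ggplot object.
#' @export
plot_rate_series <- function(estimates, reference = NULL) {
  p <- ggplot2::ggplot(estimates[estimates$detected, ],
                       ggplot2::aes(.data$window_start_s, .data$rate_bpm)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "window start (s)", y = "rate (BPM)")
  if (!is.null(reference)) {
    p <- p + ggplot2::geom_line(
      data = reference[reference$detected, ],
      ggplot2::aes(.data$window_start_s, .data$rate_bpm),
      colour = "grey30"
    )
  }
  p
}
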