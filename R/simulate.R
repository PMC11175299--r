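# Synthetic range-time radar signals and matched reference channels.

# One breathing cycle sampled at fractional phase u in [0, 1); returns a
# displacement profile in [0, 1] (0 = end-expiratory rest, 1 = full
# inspiration). All shapes are C1-continuous; "raised" breathes in faster
# than out, "sharp" adds an end-expiratory pause whose harmonics reach the
# heart band.
breath_cycle <- function(u, shape = c("raised", "sine", "sharp")) {
  shape <- match.arg(shape)
  u <- u %% 1
  if (shape == "sine") {
    return(0.5 * (1 - cos(2 * pi * u)))
  }
  if (shape == "raised") {
    a <- 0.4
    return(ifelse(u < a,
                  0.5 * (1 - cos(pi * u / a)),
                  0.5 * (1 + cos(pi * (u - a) / (1 - a)))))
  }
  # sharp: brisk inhale 0-0.2, exhale 0.2-0.45, end-expiratory pause 0.45-1
  out <- numeric(length(u))
  i1 <- u < 0.20
  i2 <- !i1 & u < 0.45
  out[i1] <- 0.5 * (1 - cos(pi * u[i1] / 0.20))
  out[i2] <- 0.5 * (1 + cos(pi * (u[i2] - 0.20) / 0.25))
  out
}

# Smooth unipolar pulse of width `width` seconds evaluated at offsets tau.
heart_pulse <- function(tau, width = 0.30) {
  ifelse(tau >= 0 & tau <= width, 0.5 * (1 - cos(2 * pi * tau / width)), 0)
}

# Cardiac trigger times (s) from an instantaneous heart-rate track (BPM).
cardiac_triggers <- function(hr_bpm, fs) {
  v <- cumsum(hr_bpm / 60) / fs # cardiac phase in beats
  n_beats <- floor(v[length(v)])
  if (n_beats < 1) return(numeric(0))
  t <- (seq_along(v) - 1) / fs
  stats::approx(v, t, xout = seq_len(n_beats), ties = "ordered")$y
}

# Sample a pulse train at frame times for one zone delay.
pulse_train <- function(triggers, delay, n, fs, width = 0.30) {
  out <- numeric(n)
  w_samp <- ceiling(width * fs)
  for (tk in triggers + delay) {
    i0 <- floor(tk * fs) + 1L
    idx <- i0:(i0 + w_samp)
    idx <- idx[idx >= 1 & idx <= n]
    if (length(idx)) {
      out[idx] <- out[idx] + heart_pulse((idx - 1) / fs - tk, width)
    }
  }
  out
}

mexican_hat <- function(tau, sigma = 0.02) {
  (1 - (tau / sigma)^2) * exp(-tau^2 / (2 * sigma^2))
}

#' Simulate a radar recording with matched reference channels
#'
#' Generates the per-bin phase-displacement and magnitude matrices an FMCW
#' radar would observe for the given scenario, together with reference
#' channels: a piezoresistive-belt-like thorax breathing signal at 32 Hz, a
#' QRS-train ECG-like signal at 256 Hz, and per-window ground-truth rate
#' tracks on the standard 60 s / 40 s-overlap analysis grid.
#'
#' Sign conventions follow the radar phase reading: motion towards the radar
#' decreases displacement, so inhalation (torso moving towards a foot-end,
#' nightstand, or ceiling radar alike) produces a falling displacement, while
#' the belt reads positively with inflation.
#'
#' @param scenario A [make_scenario()] object.
#' @param config A [radar_config()]; its shell depth sets the bin spacing and
#'   its frame rate the slow-time sampling.
#' @return A list with elements `signal` (class `range_time_signal`:
#'   `displacement` and `magnitude` matrices of size bins x frames,
#'   `bin_ranges`, `frame_rate`, zone map and metadata) and `reference`
#'   (class `reference_channels`: `belt`, `belt_fs`, `ecg`, `ecg_fs`,
#'   `triggers`, and a `truth` tibble with columns `window_start_s`,
#'   `truth_breathing_bpm`, `truth_heart_bpm`, `present`).
#' @examples
#' sim <- simulate_recording(make_scenario("foot_end", list(duration = 120), seed = 2))
#' dim(sim$signal$displacement)
#' @export
simulate_recording <- function(scenario, config = radar_config()) {
  stopifnot(inherits(scenario, "radar_scenario"))
  fs <- config$frame_rate
  if (fs != scenario$frame_rate) {
    stop("scenario frame rate (", scenario$frame_rate,
         " Hz) does not match radar config (", fs, " Hz)", call. = FALSE)
  }
  n <- round(scenario$duration * fs)
  t <- (seq_len(n) - 1) / fs
  d_shell <- shell_depth(config)
  n_bins <- floor(scenario$max_range_sim / d_shell)
  bin_ranges <- (seq_len(n_bins) - 0.5) * d_shell

  with_seed(scenario$seed + 1L, {
    # breathing displacement profile (0..1), common phase for all zones
    u <- cumsum(scenario$breathing_rate_bpm / 60) / fs
    breath <- breath_cycle(u, scenario$breathing_shape)
    triggers <- cardiac_triggers(scenario$heart_rate_bpm, fs)

    present <- rep(TRUE, n)
    for (iv in scenario$absence_intervals) {
      present[t >= iv[1] & t < iv[2]] <- FALSE
    }

    displacement <- matrix(0, n_bins, n)
    body_motion <- matrix(0, n_bins, n) # clean |motion| for magnitude model
    zones <- scenario$zones
    trains <- lapply(unique(zones$pulse_delay), pulse_train,
                     triggers = triggers, n = n, fs = fs)
    names(trains) <- as.character(unique(zones$pulse_delay))
    for (k in seq_len(nrow(zones))) {
      bins <- which(bin_ranges >= zones$near_m[k] & bin_ranges <= zones$far_m[k])
      if (!length(bins)) next
      wave <- -(zones$breathing_gain[k] * scenario$breathing_amplitude * breath +
                  zones$heartbeat_gain[k] * scenario$heartbeat_amplitude *
                    trains[[as.character(zones$pulse_delay[k])]])
      wave <- wave * present
      for (b in bins) {
        displacement[b, ] <- displacement[b, ] + wave
        body_motion[b, ] <- body_motion[b, ] +
          zones$magnitude_gain[k] * abs(wave)
      }
    }
    displacement <- displacement +
      matrix(stats::rnorm(n_bins * n, sd = scenario$noise_sd), n_bins, n)

    clutter <- stats::runif(n_bins, 0.5, 1.5)
    magnitude <- clutter + 80 * body_motion +
      matrix(stats::rnorm(n_bins * n, sd = 0.01), n_bins, n)

    # reference channels
    belt_fs <- 32
    t_belt <- seq(0, scenario$duration - 1 / belt_fs, by = 1 / belt_fs)
    br_belt <- stats::approx(t, scenario$breathing_rate_bpm, xout = t_belt,
                             rule = 2, ties = "ordered")$y
    u_belt <- cumsum(br_belt / 60) / belt_fs
    belt <- scenario$breathing_amplitude *
      breath_cycle(u_belt, scenario$breathing_shape) +
      stats::rnorm(length(t_belt), sd = 0.02 * scenario$breathing_amplitude)

    ecg_fs <- 256
    n_ecg <- round(scenario$duration * ecg_fs)
    t_ecg <- (seq_len(n_ecg) - 1) / ecg_fs
    ecg <- stats::rnorm(n_ecg, sd = 0.02) +
      0.05 * sin(2 * pi * 0.3 * t_ecg) # mild baseline wander
    for (tk in triggers) {
      i0 <- round(tk * ecg_fs) + 1L
      idx <- (i0 - 16L):(i0 + 16L)
      idx <- idx[idx >= 1 & idx <= n_ecg]
      if (length(idx)) ecg[idx] <- ecg[idx] + mexican_hat((idx - 1) / ecg_fs - tk)
    }
  })

  starts <- make_windows(scenario$duration)
  truth <- tibble::tibble(
    window_start_s = starts,
    truth_breathing_bpm = vapply(starts, function(s) {
      mean(scenario$breathing_rate_bpm[t >= s & t < s + 60])
    }, numeric(1)),
    truth_heart_bpm = vapply(starts, function(s) {
      mean(scenario$heart_rate_bpm[t >= s & t < s + 60])
    }, numeric(1)),
    present = vapply(starts, function(s) {
      all(present[t >= s & t < s + 60])
    }, logical(1))
  )

  signal <- structure(
    list(
      displacement = displacement,
      magnitude = magnitude,
      bin_ranges = bin_ranges,
      frame_rate = fs,
      duration = scenario$duration,
      position = scenario$position,
      seed = scenario$seed,
      zones = zones
    ),
    class = "range_time_signal"
  )
  signal <- inject_artifacts(signal, scenario$artifact_schedule)

  reference <- structure(
    list(belt = belt, belt_fs = belt_fs, ecg = ecg, ecg_fs = ecg_fs,
         triggers = triggers, truth = truth),
    class = "reference_channels"
  )
  list(signal = signal, reference = reference)
}

#' @export
print.range_time_signal <- function(x, ...) {
  cat(sprintf("<range_time_signal> %d bins x %d frames @ %g Hz (%s, seed %s)\n",
              nrow(x$displacement), ncol(x$displacement), x$frame_rate,
              x$position %||% "?", x$seed %||% "?"))
  invisible(x)
}

#' Inject large-motion artifacts into a range-time signal
#'
#' Adds triangular ramp motions whose sample-to-sample displacement step
#' equals the requested amplitude to the bins of a named body zone (or all
#' bins) during each event. Used to emulate limb movements and other large
#' body motions that the artifact gate must reject.
#'
#' @param signal A `range_time_signal`.
#' @param schedule List of events, each a list/vector with fields `start`
#'   (s), `duration` (s), `zone` (a zone name or `"all"`), and `amplitude`
#'   (m per sample step).
#' @return The signal with artifacts added; an empty schedule returns the
#'   input unchanged.
#' @export
inject_artifacts <- function(signal, schedule) {
  stopifnot(inherits(signal, "range_time_signal"))
  if (!length(schedule)) return(signal)
  n <- ncol(signal$displacement)
  fs <- signal$frame_rate
  for (ev in schedule) {
    ev <- as.list(ev)
    start <- as.numeric(ev$start)
    dur <- as.numeric(ev$duration)
    amp <- as.numeric(ev$amplitude)
    if (start < 0 || start + dur > n / fs) {
      stop("artifact event [", start, ", ", start + dur,
           "] s lies outside the recording", call. = FALSE)
    }
    bins <- if (identical(ev$zone, "all")) {
      seq_along(signal$bin_ranges)
    } else {
      z <- signal$zones[signal$zones$zone == ev$zone, ]
      if (nrow(z) == 0) stop("unknown zone: ", ev$zone, call. = FALSE)
      which(signal$bin_ranges >= min(z$near_m) &
              signal$bin_ranges <= max(z$far_m))
    }
    idx <- (floor(start * fs) + 1L):min(n, floor((start + dur) * fs) + 1L)
    m <- length(idx)
    if (m < 2) next
    up <- ceiling(m / 2)
    ramp <- amp * cumsum(c(rep(1, up), rep(-1, m - up)))
    for (b in bins) {
      signal$displacement[b, idx] <- signal$displacement[b, idx] + ramp
    }
  }
  signal
}

`%||%` <- function(a, b) if (is.null(a)) b else a
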