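# Internal signal-processing helpers shared by the bin-selection and
# rate-estimation stages.

# Cache of Butterworth designs keyed by (band, fs, order); designing the
# filter once per band avoids repeating signal::butter in per-bin loops.
.butter_cache <- new.env(parent = emptyenv())

butter_bandpass <- function(band, fs, order = 2) {
  key <- paste(order, fs, band[1], band[2], sep = "_")
  flt <- .butter_cache[[key]]
  if (is.null(flt)) {
    flt <- signal::butter(order, c(band[1], band[2]) / (fs / 2), type = "pass")
    .butter_cache[[key]] <- flt
  }
  flt
}

# Zero-phase (forward-backward) second-order Butterworth bandpass. Zero-phase
# filtering keeps all range bins time-aligned, which matters when comparing
# bins and when pairing radar against reference windows.
bandpass <- function(x, fs, band, order = 2) {
  flt <- butter_bandpass(band, fs, order)
  signal::filtfilt(flt, x)
}

# Magnitude of the analytic signal (Hilbert envelope) via the FFT
# construction: double positive frequencies, zero negative ones.
analytic_envelope <- function(x) {
  n <- length(x)
  if (n == 0) return(numeric(0))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

# Local maxima with a minimum topographic prominence and a minimum peak
# separation (in samples). Peaks are accepted greedily in order of height,
# mirroring the usual find-peaks semantics.
find_peaks <- function(x, min_prominence = 0, min_distance = 1L) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(cand) == 0) return(integer(0))
  if (min_prominence > 0) {
    keep <- vapply(cand, function(i) {
      left <- if (i > 1) {
        higher <- which(x[1:(i - 1)] > x[i])
        lo <- if (length(higher)) max(higher) + 1L else 1L
        min(x[lo:(i - 1)])
      } else x[i]
      right <- if (i < n) {
        higher <- which(x[(i + 1):n] > x[i])
        hi <- if (length(higher)) i + min(higher) - 1L else n
        min(x[(i + 1):hi])
      } else x[i]
      (x[i] - max(left, right)) >= min_prominence
    }, logical(1))
    cand <- cand[keep]
  }
  if (length(cand) == 0) return(integer(0))
  if (min_distance > 1L && length(cand) > 1L) {
    ord <- cand[order(x[cand], decreasing = TRUE)]
    taken <- integer(0)
    for (i in ord) {
      if (all(abs(i - taken) >= min_distance)) taken <- c(taken, i)
    }
    cand <- sort(taken)
  }
  cand
}

# Sub-sample peak locations (s) by parabolic interpolation through the
# peak sample and its neighbours.
peak_times <- function(x, peaks, fs) {
  n <- length(x)
  vapply(peaks, function(i) {
    if (i <= 1 || i >= n) return((i - 1) / fs)
    denom <- x[i - 1] - 2 * x[i] + x[i + 1]
    delta <- if (abs(denom) < 1e-12) 0 else 0.5 * (x[i - 1] - x[i + 1]) / denom
    (i - 1 + max(-0.5, min(0.5, delta))) / fs
  }, numeric(1))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
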