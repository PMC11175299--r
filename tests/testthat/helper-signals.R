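# Shared fixtures: all test signals are generated in code.

tone <- function(freq_hz, fs, duration_s = 60, amp = 1, phase = 0) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  amp * sin(2 * pi * freq_hz * t + phase)
}

# Minimal range-time signal wrapper around a displacement matrix.
as_rts <- function(displacement, magnitude = NULL, fs = 20,
                   bin_ranges = NULL, zones = NULL) {
  n_bins <- nrow(displacement)
  structure(
    list(
      displacement = displacement,
      magnitude = magnitude %||%
        matrix(1, n_bins, ncol(displacement)),
      bin_ranges = bin_ranges %||% ((seq_len(n_bins) - 0.5) * 0.05),
      frame_rate = fs,
      duration = ncol(displacement) / fs,
      position = "test", seed = 0L,
      zones = zones
    ),
    class = "range_time_signal"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force double-loop autocorrelation oracle (direct per-lag evaluation).
acf_oracle <- function(x, k_max) {
  n <- length(x)
  vapply(0:k_max, function(k) {
    if (k == 0) return(1)
    a <- x[(k + 1):n]
    b <- x[1:(n - k)]
    ma <- mean(a); mb <- mean(b)
    num <- 0
    for (i in seq_along(a)) num <- num + (a[i] - ma) * (b[i] - mb)
    num / (length(a) - 1) / (sd(a) * sd(b))
  }, numeric(1))
}

# Brute-force TPC oracle: direct sum over the aligned segments.
tpc_oracle <- function(p, T_samp) {
  n <- length(p)
  s <- 0
  for (i in (T_samp + 1):n) s <- s + p[i] * p[i - T_samp]
  a <- p[(T_samp + 1):n]
  b <- p[1:(n - T_samp)]
  s / (sd(a) * sd(b)) / (length(a) - 1)
}
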