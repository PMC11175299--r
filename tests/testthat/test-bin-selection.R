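test_that("spatial gate keeps the closed interval [0.45, 3] m and is idempotent", {
  cfg <- radar_config()
  sig <- as_rts(matrix(rnorm(5 * 40), 5, 40),
                bin_ranges = c(0.30, 0.45, 1.00, 3.00, 3.50))
  g <- spatial_gate(sig, cfg)
  expect_equal(g$bin_ranges, c(0.45, 1.00, 3.00)) # boundaries kept
  expect_equal(attr(g, "orig_bin"), c(2L, 3L, 4L))
  g2 <- spatial_gate(g, cfg)
  expect_equal(g2$bin_ranges, g$bin_ranges)
  expect_equal(g2$displacement, g$displacement)
  # nothing survives -> empty result, not an error
  far <- spatial_gate(as_rts(matrix(0, 2, 40), bin_ranges = c(3.2, 3.4)), cfg)
  expect_equal(nrow(far$displacement), 0)
})

test_that("artifact gate works per bin with a 1 mm sample step threshold", {
  calm <- matrix(0, 3, 100)
  expect_true(all(artifact_gate(calm)$pass))
  jumpy <- calm
  jumpy[, 50] <- 2e-3 # 2 mm step up and down in every bin
  res <- artifact_gate(jumpy)
  expect_true(res$all_failed)
  # moving legs, calm torso: only the moving bin fails
  mixed <- calm
  mixed[1, 50] <- 2e-3
  res <- artifact_gate(mixed)
  expect_equal(res$pass, c(FALSE, TRUE, TRUE))
  expect_false(res$all_failed)
  # exactly at threshold passes (strict inequality for failure)
  at <- calm
  at[2, 10] <- 1e-3
  expect_true(artifact_gate(at)$pass[2])
})

test_that("magnitude variability screen picks fluctuating bins with halo", {
  set.seed(1)
  mag <- matrix(1, 9, 200)
  mag[5, ] <- 1 + sin(seq(0, 20, length.out = 200))
  expect_equal(magnitude_variability_candidates(mag, k_top = 1, halo = 2),
               3:7)
  # all-constant magnitudes: SD ties -> lowest indices win
  flat <- matrix(1, 9, 200)
  expect_equal(magnitude_variability_candidates(flat, k_top = 2, halo = 0),
               1:2)
  # halo is clipped to eligible bins
  expect_equal(magnitude_variability_candidates(mag, k_top = 1, halo = 2,
                                                eligible = 4:9), 4:7)
})

test_that("normalized phase recovers the period and stays bounded", {
  fs <- 20
  nw <- normalize_phase(tone(0.25, fs, 60, amp = 2e-3), fs, "breathing")
  expect_equal(nw$period_T, 4.0, tolerance = 1 / (4 * fs))
  expect_lte(max(abs(nw$p_hat)), 1 + 1e-6)
  # constant input -> no periodicity
  expect_null(normalize_phase(rep(0.5, 1200), fs, "breathing"))
  # noisy 1 Hz in the heart band: period within 5% (Monte Carlo)
  errs <- vapply(1:20, function(s) {
    x <- with_seed(s, tone(1.0, fs, 60) + rnorm(1200, sd = 0.1))
    normalize_phase(x, fs, "heartbeat")$period_T
  }, numeric(1))
  expect_lt(max(abs(errs - 1.0)), 0.05)
})

test_that("TPC matches its definition: +1 at the period, -1 at half period", {
  fs <- 20
  nw <- normalize_phase(tone(0.25, fs, 60, amp = 1e-3), fs, "breathing")
  expect_equal(temporal_phase_coherency(nw), 1, tolerance = 0.02)
  expect_equal(temporal_phase_coherency(nw, period_T = 2.0), -1,
               tolerance = 0.02)
  # white noise scores low
  nulls <- vapply(1:25, function(s) {
    p <- with_seed(s, rnorm(1200))
    nw0 <- list(p_hat = p, period_T = 1.0, fs = fs, band = c(0.8, 1.7))
    temporal_phase_coherency(nw0, period_T = 1.0)
  }, numeric(1))
  expect_lt(max(abs(nulls)), 0.2)
  # constant segments fail
  expect_true(is.na(temporal_phase_coherency(
    list(p_hat = rep(1, 100), period_T = 1, fs = fs), period_T = 1
  )))
})

test_that("TPC equals the brute-force double-loop evaluation", {
  fs <- 20
  for (s in 1:5) {
    x <- with_seed(s, rnorm(1200, sd = 1e-3))
    nw <- normalize_phase(x, fs, "breathing")
    expect_false(is.null(nw)) # noise always has many crossings
    T_samp <- round(nw$period_T * fs)
    expect_equal(temporal_phase_coherency(nw),
                 tpc_oracle(nw$p_hat, T_samp), tolerance = 1e-10)
  }
})

test_that("candidate selection returns top-scored bins and failure reasons", {
  fs <- 20
  n <- 1200
  breath <- -2e-3 * (0.5 - 0.5 * cos(2 * pi * 0.25 * (0:(n - 1)) / fs))
  disp <- with_seed(9, rbind(
    rnorm(n, sd = 1e-5),
    breath + rnorm(n, sd = 1e-5),
    rnorm(n, sd = 1e-5)
  ))
  mag <- rbind(matrix(1, 1, n), 1 + 50 * abs(breath), matrix(1, 1, n))
  win <- as_rts(disp, magnitude = mag, bin_ranges = c(1.0, 1.05, 1.10))
  win$window_start <- 0
  cs <- select_bins(win, "breathing")
  expect_equal(cs$empty_reason, "none")
  expect_equal(cs$bins$bin_index[1], 2L)
  # all-artifact window
  jump <- matrix(rep(c(0, 2e-3), length.out = n), 3, n, byrow = TRUE)
  wa <- as_rts(jump, bin_ranges = c(1, 1.05, 1.1))
  expect_equal(select_bins(wa, "breathing")$empty_reason, "all_bins_artifact")
  # constant signals -> no periodicity
  wc <- as_rts(matrix(1e-4, 2, n), bin_ranges = c(1, 1.05))
  expect_equal(select_bins(wc, "heartbeat")$empty_reason, "no_periodicity")
})

test_that("heartbeat selection ignores the magnitude signal entirely", {
  sc <- make_scenario("foot_end", list(duration = 60), seed = 12)
  sim <- simulate_recording(sc)
  win <- slice_window(spatial_gate(sim$signal), 0)
  cs1 <- select_bins(win, "heartbeat")
  win2 <- win
  win2$magnitude <- with_seed(1, matrix(runif(length(win$magnitude)),
                                        nrow(win$magnitude)))
  cs2 <- select_bins(win2, "heartbeat")
  expect_identical(cs1$bins, cs2$bins)
})

test_that("breathing candidates hit the true torso on simulated nights", {
  hits <- 0
  n_win <- 20
  for (s in seq_len(n_win)) {
    sc <- make_scenario("foot_end",
                        list(duration = 60, noise_sd = 1e-5), seed = 100 + s)
    sim <- simulate_recording(sc)
    win <- slice_window(spatial_gate(sim$signal), 0)
    cs <- select_bins(win, "breathing")
    if (cs$empty_reason != "none") next
    torso <- sim$signal$bin_ranges >= 1.40 & sim$signal$bin_ranges <= 1.95
    if (cs$bins$range_m[1] >= 1.40 && cs$bins$range_m[1] <= 1.95) hits <- hits + 1
  }
  expect_gte(hits / n_win, 0.95)
})
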