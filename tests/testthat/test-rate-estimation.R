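test_that("autocorrelogram is a per-lag Pearson correlation", {
  fs <- 20
  x <- tone(0.25, fs, 60)
  ac <- autocorrelogram(x, fs, max_lag_s = 10)
  expect_equal(ac$rho[1], 1)
  expect_true(all(abs(ac$rho) <= 1 + 1e-12, na.rm = TRUE))
  # first non-zero-lag peak of a 0.25 Hz tone sits at k = 80 samples (4 s)
  peaks <- which(diff(sign(diff(ac$rho))) == -2) + 1
  first <- peaks[ac$lag_s[peaks] > 1][1]
  expect_equal(ac$lag_s[first], 4.0, tolerance = 1 / fs)
  # brute-force double-loop oracle equality
  for (s in 1:3) {
    y <- with_seed(s, rnorm(300))
    ac2 <- autocorrelogram(y, fs, max_lag_s = 2.5)
    expect_equal(ac2$rho, acf_oracle(y, 50), tolerance = 1e-10)
  }
  expect_error(autocorrelogram(rep(1, 100), fs), "zero-variance")
})

test_that("middle-peak width test separates breathing from drift and noise", {
  fs <- 20
  # 0.25 Hz tone: troughs at +/-2 s -> width 4 s
  expect_true(middle_peak_width_test(autocorrelogram(tone(0.25, fs, 60), fs)))
  # slow drift: no trough inside the lag horizon at breathing widths
  drift <- tone(0.02, fs, 60)
  expect_false(middle_peak_width_test(autocorrelogram(drift, fs)))
  # white noise collapses the middle peak: width below 2.5 s almost surely
  fails <- vapply(1:40, function(s) {
    !middle_peak_width_test(autocorrelogram(with_seed(s, rnorm(1200)), fs))
  }, logical(1))
  expect_gte(mean(fails), 0.95)
})

test_that("breathing rate is the inverse first autocorrelation peak", {
  fs <- 20
  est <- breathing_rate_from_signal(tone(0.25, fs, 60, amp = 1e-3), fs)
  expect_true(est$detected)
  expect_equal(est$rate_bpm, 15.0, tolerance = 1e-6)
  # raised-cosine breathing at 0.2 Hz from the simulator, noiseless
  sc <- make_scenario("foot_end",
                      list(duration = 60, noise_sd = 0,
                           breathing_rate_bpm = 12, heart_rate_bpm = 70),
                      seed = 1)
  sim <- simulate_recording(sc)
  thorax <- which(sim$signal$bin_ranges >= 1.70 & sim$signal$bin_ranges <= 1.95)[1]
  est2 <- breathing_rate_from_signal(sim$signal$displacement[thorax, ], fs)
  expect_true(est2$detected)
  expect_equal(est2$rate_bpm, 12, tolerance = 1 / 12)
  # constant signal is never detected
  expect_false(breathing_rate_from_signal(rep(0, 1200), fs)$detected)
})

test_that("breathing choice prefers clear consistent candidates", {
  one <- tibble::tibble(detected = TRUE, rate_bpm = 15, quality_rho = 0.9,
                        quality_sd = 0.1, fail_reason = "none",
                        bin_index = 3L, range_m = 0.6, tpc_score = 0.9)
  expect_equal(choose_breathing_estimate(one)$bin_index, 3L)
  two <- dplyr::bind_rows(one, dplyr::mutate(one, quality_rho = 0.7,
                                             bin_index = 2L))
  expect_equal(choose_breathing_estimate(two)$bin_index, 3L)
  none <- dplyr::mutate(one, detected = FALSE)
  expect_false(choose_breathing_estimate(none)$detected)
  # clean bin beats noisy bin on simulated data
  fs <- 20
  wins <- 0
  for (s in 1:20) {
    clean <- with_seed(s, tone(0.25, fs, 60, amp = 1e-3) + rnorm(1200, sd = 2e-5))
    noisy <- with_seed(s + 1000, tone(0.25, fs, 60, amp = 1e-3) +
                         rnorm(1200, sd = 8e-4))
    frags <- dplyr::bind_rows(
      dplyr::mutate(breathing_rate_from_signal(clean, fs), bin_index = 1L,
                    range_m = 1.0, tpc_score = 0.9),
      dplyr::mutate(breathing_rate_from_signal(noisy, fs), bin_index = 2L,
                    range_m = 1.1, tpc_score = 0.8)
    )
    if (choose_breathing_estimate(frags)$bin_index == 1L) wins <- wins + 1
  }
  expect_gte(wins / 20, 0.9)
})

test_that("heart rate comes from median-filtered peak intervals", {
  fs <- 20
  # clean 1 Hz pulse train normalised to (-1, 1)
  nw <- normalize_phase(tone(1.0, fs, 60, amp = 4e-4), fs, "heartbeat")
  est <- heart_rate_from_bin(nw)
  expect_true(est$detected)
  expect_equal(est$rate_bpm, 60, tolerance = 1e-2)
  # a missing pulse is repaired by the kernel-3 median filter
  t <- seq(0, 59.95, by = 1 / fs)
  beats <- setdiff(0:58, 30) # one beat missing
  x <- rowSums(vapply(beats, function(b) {
    ifelse(t >= b & t <= b + 0.3,
           0.5 * (1 - cos(2 * pi * (t - b) / 0.3)), 0)
  }, numeric(length(t))))
  nw2 <- normalize_phase(4e-4 * x, fs, "heartbeat")
  est2 <- heart_rate_from_bin(nw2)
  expect_true(est2$detected)
  expect_equal(est2$rate_bpm, 60, tolerance = 2 / 60)
  # far-out-of-band trains are discarded: feed synthetic peaks directly
  fast <- list(p_hat = tone(2.5, 10, 60), fs = 10, band = c(0.8, 1.7),
               period_T = 0.4)
  est3 <- heart_rate_from_bin(fast)
  expect_false(est3$detected)
  expect_equal(est3$fail_reason, "outside_physiological_range")
  # too few peaks
  expect_false(heart_rate_from_bin(list(p_hat = rep(0, 100), fs = fs,
                                        band = c(0.8, 1.7)))$detected)
})

test_that("heart choice minimises interval SD with TPC tie-break", {
  a <- tibble::tibble(detected = TRUE, rate_bpm = 60, quality_sd = 0.010,
                      fail_reason = "none", bin_index = 5L, range_m = 1,
                      tpc_score = 0.5)
  b <- dplyr::mutate(a, quality_sd = 0.040, bin_index = 2L, tpc_score = 0.9)
  expect_equal(choose_heart_estimate(dplyr::bind_rows(a, b))$bin_index, 5L)
  tie <- dplyr::mutate(a, bin_index = 9L, tpc_score = 0.95)
  expect_equal(choose_heart_estimate(dplyr::bind_rows(a, tie))$bin_index, 9L)
  expect_false(choose_heart_estimate(dplyr::mutate(a, detected = FALSE))$detected)
})

test_that("rates on constant-rate noiseless input are within 1 BPM of truth", {
  fs <- 20
  for (br in c(8, 15, 22)) {
    est <- breathing_rate_from_signal(tone(br / 60, fs, 60, amp = 2e-3), fs)
    expect_true(est$detected)
    expect_lt(abs(est$rate_bpm - br), 1)
  }
  for (hr in c(55, 72, 100)) {
    sc <- make_scenario("foot_end",
                        list(duration = 60, noise_sd = 0, heart_rate_bpm = hr,
                             breathing_rate_bpm = 14), seed = hr)
    sim <- simulate_recording(sc)
    legs <- which(sim$signal$bin_ranges >= 0.95 & sim$signal$bin_ranges <= 1.3)[1]
    nw <- normalize_phase(sim$signal$displacement[legs, ], fs, "heartbeat")
    est <- heart_rate_from_bin(nw)
    expect_true(est$detected)
    expect_lt(abs(est$rate_bpm - hr), 1)
  }
  # just above 48 BPM the pulse's 2nd harmonic sits inside the heart band
  # and creates secondary peaks; the bias stays bounded but can exceed 1 BPM
  sc <- make_scenario("foot_end",
                      list(duration = 60, noise_sd = 0, heart_rate_bpm = 50,
                           breathing_rate_bpm = 14), seed = 50)
  sim <- simulate_recording(sc)
  est <- extract_vitals(sim$signal, mode = "heartbeat")
  expect_lt(abs(est$rate_bpm[1] - 50), 2.5)
})

test_that("detection rate degrades monotonically with noise", {
  fs <- 20
  noise_levels <- c(0, 1e-4, 3e-4, 1e-3)
  det <- vapply(noise_levels, function(ns) {
    hits <- vapply(1:15, function(s) {
      sc <- make_scenario("foot_end",
                          list(duration = 60, noise_sd = ns), seed = 300 + s)
      sim <- simulate_recording(sc)
      hr <- extract_vitals(sim$signal, mode = "heartbeat")
      hr$detected[1]
    }, logical(1))
    mean(hits)
  }, numeric(1))
  # non-increasing, allowing one small inversion
  viol <- diff(det) > 0.02 + 1e-9
  expect_lte(sum(viol), 1)
})
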