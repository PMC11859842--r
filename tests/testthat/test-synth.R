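# Synthetic session generator: determinism, latent-trace dynamics, and
# ground-truth fidelity of each channel.

test_that("latent trace is flat without events and steps at an event", {
  spec_flat <- session_spec(duration_s = 300,
                            events = tibble::tibble(label = character(0),
                                                    time_s = numeric(0)),
                            noci_noise_sd = 0, seed = 1)
  tr <- gen_noci_trace(spec_flat)
  expect_true(all(tr$noci == spec_flat$baseline_noci))

  spec_ev <- session_spec(duration_s = 600,
                          events = tibble::tibble(label = "t2", time_s = 300),
                          noci_step = 15, noci_noise_sd = 0, seed = 1)
  tr <- gen_noci_trace(spec_ev)
  pre <- mean(tr$noci[tr$time_s >= 120 & tr$time_s < 300])
  post <- mean(tr$noci[tr$time_s > 300 & tr$time_s <= 480])
  # mean kernel response over 180 s: rise (5..25 s) + decay (30..180 s),
  # computed by direct summation of the 30 s linear rise / tau = 300 s decay
  u <- seq(5, 180, by = 5)
  expected <- 15 * mean(ifelse(u < 30, u / 30, exp(-(u - 30) / 300)))
  expect_equal(post - pre, expected, tolerance = 1e-10)
  expect_gte(post - pre, 10)
  expect_lte(post - pre, 15)
})

test_that("trace stays within the 0-100 score scale and event validation works", {
  spec <- session_spec(duration_s = 400, baseline_noci = 95, noci_step = 30,
                       events = tibble::tibble(label = "t1", time_s = 200),
                       seed = 3)
  expect_true(all(gen_noci_trace(spec)$noci <= 100))
  expect_error(
    session_spec(duration_s = 400,
                 events = tibble::tibble(label = "t1", time_s = 30)),
    "event times"
  )
})

test_that("identical seeds give bit-identical session bundles", {
  spec <- session_spec(duration_s = 200,
                       events = tibble::tibble(label = "t1", time_s = 100),
                       seed = 42)
  b1 <- simulate_session(spec)
  b2 <- simulate_session(spec)
  expect_identical(b1$ecg$samples, b2$ecg$samples)
  expect_identical(b1$ppg$samples, b2$ppg$samples)
  expect_identical(b1$eeg$samples, b2$eeg$samples)
  expect_identical(b1$raters, b2$raters)
  expect_identical(b1$truth_noci, b2$truth_noci)
  b3 <- simulate_session(session_spec(duration_s = 200,
                                      events = spec$events, seed = 43))
  expect_false(identical(b1$eeg$samples, b3$eeg$samples))
})

test_that("all generated channels are finite and the trace is bounded", {
  b <- small_session()
  expect_false(anyNA(b$ecg$samples) || any(!is.finite(b$ecg$samples)))
  expect_false(anyNA(b$ppg$samples) || any(!is.finite(b$ppg$samples)))
  expect_false(anyNA(b$eeg$samples) || any(!is.finite(b$eeg$samples)))
  expect_true(all(b$truth_noci$noci >= 0 & b$truth_noci$noci <= 100))
})

test_that("ECG beat count matches heart rate and RR carries the HF modulation", {
  spec <- session_spec(duration_s = 200, baseline_hr = 60, hf_mod_freq = 0.3,
                       events = tibble::tibble(label = character(0),
                                               time_s = numeric(0)),
                       noci_noise_sd = 0, seed = 5)
  tr <- gen_noci_trace(spec)
  e <- gen_ecg(spec, tr)
  in_16s <- sum(e$r_times_s >= 10 & e$r_times_s < 26)
  expect_gte(in_16s, 15)
  expect_lte(in_16s, 17)
  # periodogram of the RR tachogram peaks at the modulation frequency
  rr <- diff(e$r_times_s)
  tmid <- e$r_times_s[-1]
  grid <- seq(min(tmid), max(tmid), by = 0.25)
  tach <- approx(tmid, rr, xout = grid)$y
  tach <- tach - mean(tach)
  spec_pow <- Mod(fft(tach))^2
  freqs <- (seq_along(tach) - 1) / length(tach) * 4
  sub <- freqs > 0.05 & freqs < 2
  peak_f <- freqs[sub][which.max(spec_pow[sub])]
  expect_lt(abs(peak_f - 0.3), 0.05)

  spec0 <- session_spec(duration_s = 200, baseline_hr = 60, hf_rr_amp = 0,
                        events = tibble::tibble(label = character(0),
                                                time_s = numeric(0)),
                        noci_noise_sd = 0, seed = 5)
  e0 <- gen_ecg(spec0, gen_noci_trace(spec0))
  expect_lt(diff(range(diff(e0$r_times_s))) * 1000, 1)  # < 1 ms spread
})

test_that("PPG amplitude ground truth matches the rendered waveform", {
  spec <- session_spec(duration_s = 150,
                       events = tibble::tibble(label = character(0),
                                               time_s = numeric(0)),
                       couplings = list(delta = 0, alpha = 0, gamma = 0,
                                        ppga = 0, ppg_width = 0, rrhf = 0),
                       noci_noise_sd = 0, seed = 6)
  tr <- gen_noci_trace(spec)
  p <- gen_ppg(spec, tr, noise_sd = 0)
  expect_lt(diff(range(p$beats$amplitude)), 1e-12)  # zero coupling -> constant

  # detected peak heights on the clean signal match the stated amplitudes
  idx <- round(p$beats$time_s * spec$ppg_rate) + 1
  idx <- idx[idx > 64 & idx < length(p$signal$samples) - 64]
  heights <- vapply(idx, function(i) max(p$signal$samples[(i - 32):(i + 32)]),
                    numeric(1))
  expect_true(all(abs(heights - p$beats$amplitude[seq_along(heights)]) /
                    p$beats$amplitude[seq_along(heights)] < 0.02))
})

test_that("negative amplitude coupling yields anticorrelated per-beat amplitudes", {
  spec <- session_spec(duration_s = 500,
                       events = tibble::tibble(label = "t2", time_s = 250),
                       seed = 7)
  tr <- gen_noci_trace(spec)
  p <- gen_ppg(spec, tr)
  z <- approx(tr$time_s, tr$noci, xout = p$beats$time_s, rule = 2)$y
  expect_lt(cor(p$beats$amplitude, z), 0)
})

test_that("EEG synthesis localizes power and couples bands with the right sign", {
  spec <- session_spec(duration_s = 200,
                       events = tibble::tibble(label = character(0),
                                               time_s = numeric(0)),
                       noci_noise_sd = 0, seed = 8)
  tr <- gen_noci_trace(spec)
  alpha_only <- gen_eeg(spec, tr, base_powers = c(delta = 0, theta = 0,
                                                  alpha = 20, beta = 0, gamma = 0))
  x <- alpha_only$signal$samples
  pxx <- Mod(fft(x - mean(x)))^2
  freqs <- (seq_along(x) - 1) / length(x) * spec$eeg_rate
  half <- freqs > 0 & freqs <= spec$eeg_rate / 2
  in_band <- sum(pxx[half & freqs >= 8 & freqs <= 12])
  expect_gte(in_band / sum(pxx[half]), 0.95)

  spec_ev <- session_spec(duration_s = 900,
                          events = tibble::tibble(label = c("t1", "t2"),
                                                  time_s = c(300, 600)),
                          seed = 9)
  tr_ev <- gen_noci_trace(spec_ev)
  g <- gen_eeg(spec_ev, tr_ev)
  z <- approx(tr_ev$time_s, tr_ev$noci, xout = g$band_truth$window_end_s,
              rule = 2)$y
  expect_gt(cor(g$band_truth$delta, z), 0)
  expect_lt(cor(g$band_truth$alpha, z), 0)
})

test_that("EEG band power is stationary when the trace is constant", {
  spec <- session_spec(duration_s = 300,
                       events = tibble::tibble(label = character(0),
                                               time_s = numeric(0)),
                       noci_noise_sd = 0, seed = 10)
  g <- gen_eeg(spec, gen_noci_trace(spec))
  expect_lt(diff(range(g$band_truth$delta)) / mean(g$band_truth$delta), 1e-9)
})

test_that("rater generation honors bias, spread and clipping", {
  spec0 <- session_spec(duration_s = 300,
                        events = tibble::tibble(label = character(0),
                                                time_s = numeric(0)),
                        noci_noise_sd = 0,
                        rater_profiles = tibble::tibble(bias = 0, sd = 0),
                        rater_stagger_s = 0, seed = 11)
  tr <- gen_noci_trace(spec0)
  r0 <- gen_raters(spec0, tr)
  expect_equal(r0$score, tr$noci)

  spec5 <- session_spec(duration_s = 300,
                        events = tibble::tibble(label = character(0),
                                                time_s = numeric(0)),
                        noci_noise_sd = 0,
                        rater_profiles = tibble::tibble(bias = 5, sd = 0),
                        rater_stagger_s = 0, seed = 11)
  r5 <- gen_raters(spec5, gen_noci_trace(spec5))
  expect_equal(r5$score, tr$noci + 5)
})

test_that("two independent raters reproduce the sqrt(2) difference SD", {
  # Bland-Altman SD of differences of two independent N(., 8) raters is
  # 8 * sqrt(2); Monte-Carlo at n >= 500 should land within 15%.
  spec <- session_spec(duration_s = 3000,
                       events = tibble::tibble(label = character(0),
                                               time_s = numeric(0)),
                       baseline_noci = 50, noci_noise_sd = 0,
                       rater_profiles = tibble::tibble(bias = c(0, 0),
                                                       sd = c(8, 8)),
                       rater_stagger_s = 0, seed = 12)
  r <- gen_raters(spec, gen_noci_trace(spec))
  wide <- tidyr::pivot_wider(r, names_from = "rater_id", values_from = "score")
  d <- wide$R01 - wide$R02
  expect_gte(length(d), 500)
  expect_lt(abs(sd(d) - 8 * sqrt(2)) / (8 * sqrt(2)), 0.15)
})

test_that("session bundles round-trip through the plain-text writer", {
  b <- small_session()
  dir <- withr::local_tempdir()
  write_session(b, dir)
  ecg2 <- read_signal_csv(file.path(dir, "ecg.csv"))
  expect_equal(ecg2$rate, b$ecg$rate)
  expect_equal(ecg2$kind, "ECG")
  expect_equal(ecg2$samples, b$ecg$samples, tolerance = 1e-6)
  raters2 <- tibble::as_tibble(read.csv(file.path(dir, "raters.csv")))
  expect_equal(nrow(raters2), nrow(b$raters))
})
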