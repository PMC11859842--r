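# Feature extraction: windowing, peak detection, RRHF, PPG and EEG channels.

test_that("window grid follows the 64 s / 5 s scheme with 59 s overlap", {
  w1 <- segment_windows(64)
  expect_equal(nrow(w1), 1)
  expect_equal(c(w1$start_s, w1$end_s), c(0, 64))

  w <- segment_windows(128)
  expect_equal(nrow(w), 13)
  expect_true(all(w$end_s - w$start_s == 64))
  overlap <- w$end_s[-nrow(w)] - w$start_s[-1]
  expect_true(all(overlap == 59))

  expect_warning(w0 <- segment_windows(40), "shorter")
  expect_equal(nrow(w0), 0)
})

test_that("R-peak detection recovers >= 99% of ground-truth beats within 20 ms", {
  b <- small_session()
  det <- detect_r_peaks(b$ecg)
  truth <- b$truth_r_times
  nearest <- vapply(truth, function(t) min(abs(det - t)), numeric(1))
  expect_gte(mean(nearest <= 0.020), 0.99)
  expect_lt(length(det), length(truth) * 1.05)  # few false alarms
  expect_true(all(diff(det) > 0.2))             # refractory respected
})

test_that("R-peak detection degrades gracefully and is translation-equivariant", {
  flat <- raw_signal(rep(0, 512 * 10), 512, "ECG")
  expect_warning(p <- detect_r_peaks(flat), "Flat")
  expect_length(p, 0)

  b <- small_session()
  seg <- raw_signal(b$ecg$samples[1:(512 * 60)], 512, "ECG")
  shifted <- raw_signal(seg$samples, 512, "ECG", start_s = 7)
  p0 <- detect_r_peaks(seg)
  p7 <- detect_r_peaks(shifted)
  expect_equal(p7, p0 + 7)
})

test_that("RR intervals are successive peak differences in ms", {
  rr <- rr_from_peaks(c(0, 1, 2))
  expect_equal(rr$rr_ms, c(1000, 1000))
  rr2 <- rr_from_peaks(c(0, 0.8, 1.7))
  expect_equal(rr2$rr_ms, c(800, 900))
  expect_equal(nrow(rr_from_peaks(seq(0, 10))), 10)  # n peaks -> n-1 intervals
  expect_error(rr_from_peaks(c(1, 0.5)), "increasing")
  expect_error(rr_from_peaks(1), "two")
})

test_that("the D4 wavelet pyramid reconstructs its input exactly", {
  set.seed(1)
  x <- rnorm(256)
  dec <- nocipipe:::dwt_periodic(x, 4)
  full <- nocipipe:::dwt_reconstruct(dec, keep_levels = 1:4, n_out = 256,
                                     include_approx = TRUE)
  expect_equal(full, x, tolerance = 1e-9)
  # band split is additive: kept + discarded levels = full signal
  part_hf <- nocipipe:::dwt_reconstruct(dec, keep_levels = 3:4, n_out = 256)
  part_rest <- nocipipe:::dwt_reconstruct(dec, keep_levels = c(1, 2), n_out = 256,
                                          include_approx = TRUE)
  expect_equal(part_hf + part_rest, x, tolerance = 1e-9)
})

test_that("RRHF extraction passes in-band and rejects out-of-band modulation", {
  tt <- seq(0, 300, by = 0.25)
  rr_const <- tibble::tibble(time_s = tt, rr_ms = rep(950, length(tt)))
  expect_lt(max(abs(extract_rrhf(rr_const)$rrhf_ms)), 1e-6 * 950)

  rr_in <- tibble::tibble(time_s = tt, rr_ms = 1000 + 50 * sin(2 * pi * 0.3 * tt))
  hf <- extract_rrhf(rr_in)
  mid <- hf$rrhf_ms[hf$time_s > 30 & hf$time_s < 270]
  amp_out <- sqrt(2) * sd(mid)
  expect_lt(abs(amp_out - 50) / 50, 0.2)
  # dominant output frequency is the input modulation frequency
  pxx <- Mod(fft(mid - mean(mid)))^2
  freqs <- (seq_along(mid) - 1) / length(mid) * 4
  expect_lt(abs(freqs[which.max(pxx[freqs <= 2])] - 0.3), 0.05)

  rr_lo <- tibble::tibble(time_s = tt, rr_ms = 1000 + 50 * sin(2 * pi * 0.05 * tt))
  hf_lo <- extract_rrhf(rr_lo)
  expect_lt(var(hf_lo$rrhf_ms) / var(rr_lo$rr_ms - 1000), 0.05)

  expect_error(extract_rrhf(tibble::tibble(time_s = c(0, 10), rr_ms = c(900, 900))),
               "64 s")
})

test_that("RRHF window power matches a time-domain Parseval oracle", {
  tt <- seq(0, 128 - 0.25, by = 0.25)
  x <- sin(2 * pi * 0.3 * tt)
  rrhf <- tibble::tibble(time_s = tt, rrhf_ms = x)
  wins <- segment_windows(128)
  p <- rrhf_power(rrhf, wins)
  expect_equal(nrow(p), nrow(wins))
  # oracle: same taper, power as mean square of the tapered samples
  w <- signal::kaiser(64, 5)
  oracle_lin <- mean(vapply(1:4, function(i) {
    seg <- x[((i - 1) * 64 + 1):(i * 64)]
    sum(((seg - mean(seg)) * w)^2) / sum(w^2)
  }, numeric(1)))
  expect_lt(abs(10^(p$rrhf_ps[1] / 10) - oracle_lin) / oracle_lin, 0.05)

  # doubling the amplitude adds 10*log10(4) = 6.02 dB
  rrhf2 <- tibble::tibble(time_s = tt, rrhf_ms = 2 * x)
  p2 <- rrhf_power(rrhf2, wins)
  expect_equal(p2$rrhf_ps[1] - p$rrhf_ps[1], 10 * log10(4), tolerance = 1e-6)

  # zero series sits at the dB floor
  p0 <- rrhf_power(tibble::tibble(time_s = tt, rrhf_ms = 0 * tt), wins)
  expect_true(all(p0$rrhf_ps == -120))
})

test_that("PPG filter passes the pulse band and blocks DC and high frequency", {
  fs <- 128
  tt <- seq(0, 40 - 1 / fs, by = 1 / fs)
  const <- raw_signal(rep(3, length(tt)), fs, "PPG")
  expect_lt(max(abs(filter_ppg(const)$samples)), 1e-6)

  probe <- function(f) {
    y <- filter_ppg(raw_signal(sin(2 * pi * f * tt), fs, "PPG"))
    core <- seq(10 * fs, 30 * fs)
    20 * log10(sd(y$samples[core]) / sd(sin(2 * pi * f * tt[core])))
  }
  expect_lt(abs(probe(1.5)), 1)    # passband within 1 dB
  expect_lt(probe(30), -20)        # stopband attenuated >= 20 dB
  expect_error(filter_ppg(raw_signal(rnorm(100), 10, "PPG")), "16 Hz")
})

test_that("zero-phase filtering preserves the symmetry of a symmetric pulse", {
  fs <- 128
  n <- fs * 30
  x <- numeric(n)
  center <- n / 2
  x[(center - 300):(center + 300)] <- exp(-((-300:300) / fs)^2 / (2 * 0.08^2))
  y <- filter_ppg(raw_signal(x, fs, "PPG"))$samples
  peak <- which.max(y)
  expect_lte(abs(peak - center), 2)
  lobe <- 100
  expect_lt(max(abs(y[(peak - lobe):(peak - 1)] -
                      rev(y[(peak + 1):(peak + lobe)]))), 1e-6)
})

test_that("AMPD recovers pulse peaks with >= 99% recall and scales linearly", {
  p <- pulse_train_ppg(bpm = 60, duration_s = 60)
  pk <- detect_ppg_peaks(p$signal)
  expect_gte(nrow(pk), 59)
  expect_lte(nrow(pk), 61)
  nearest <- vapply(p$beat_times, function(t) min(abs(pk$time_s - t)), numeric(1))
  expect_gte(mean(nearest <= 0.05), 0.99)

  p2 <- raw_signal(2 * p$signal$samples, 128, "PPG")
  pk2 <- detect_ppg_peaks(p2)
  expect_equal(pk2$time_s, pk$time_s)
  expect_equal(pk2$amplitude, 2 * pk$amplitude, tolerance = 1e-12)

  flat <- raw_signal(rep(0, 128 * 20), 128, "PPG")
  expect_equal(nrow(detect_ppg_peaks(flat)), 0)
})

test_that("PPGA tracks a step in pulse amplitude over about 16 s", {
  # beats every second, amplitude 1 before t = 150, 2 after
  beats <- tibble::tibble(time_s = seq(64, 250, by = 1))
  beats$amplitude <- ifelse(beats$time_s < 150, 1, 2)
  wins <- segment_windows(250)
  ppga <- compute_ppga(beats, wins)
  expect_true(all(diff(ppga$ppga) >= -1e-12))  # monotone through the step
  expect_equal(ppga$ppga[ppga$window_end_s <= 134][1], 1)
  expect_true(all(abs(ppga$ppga[ppga$window_end_s >= 170] - 2) < 1e-12))
  # the transition spans roughly the 16 s smoothing window
  trans <- ppga$window_end_s[ppga$ppga > 1.01 & ppga$ppga < 1.99]
  expect_lte(max(trans) - min(trans), 16)

  ppga2 <- compute_ppga(dplyr::mutate(beats, amplitude = 3 * amplitude), wins)
  expect_equal(ppga2$ppga, 3 * ppga$ppga, tolerance = 1e-12)
})

test_that("PPG AUC matches the closed form for a rectified sinusoid", {
  fs <- 128
  tt <- seq(0, 128 - 1 / fs, by = 1 / fs)
  sig <- raw_signal(sin(2 * pi * 1 * tt), fs, "PPG")
  wins <- segment_windows(128)
  auc <- compute_ppg_auc(sig, wins)
  expect_equal(nrow(auc), 13)
  expect_lt(abs(auc$ppg_auc[1] - 64 * 2 / pi) / (64 * 2 / pi), 0.005)
  auc2 <- compute_ppg_auc(raw_signal(2 * sig$samples, fs, "PPG"), wins)
  expect_equal(auc2$ppg_auc, 2 * auc$ppg_auc, tolerance = 1e-12)
  zero <- compute_ppg_auc(raw_signal(rep(0, length(tt)), fs, "PPG"), wins)
  expect_true(all(zero$ppg_auc == 0))
})

test_that("EEG filter keeps 10 Hz, removes DC and attenuates 60 Hz", {
  fs <- 128
  tt <- seq(0, 30 - 1 / fs, by = 1 / fs)
  expect_lt(max(abs(filter_eeg(raw_signal(rep(5, length(tt)), fs, "EEG"))$samples)),
            1e-3)
  probe <- function(f) {
    y <- filter_eeg(raw_signal(sin(2 * pi * f * tt), fs, "EEG"))
    core <- seq(10 * fs, 25 * fs)
    20 * log10(sd(y$samples[core]) / sd(sin(2 * pi * f * tt[core])))
  }
  expect_lt(abs(probe(10)), 1)
  expect_lt(probe(60), -20)
  expect_error(filter_eeg(raw_signal(rnorm(100), 50, "EEG")), "96 Hz")
})

test_that("a pure 10 Hz tone concentrates band power in alpha", {
  fs <- 128
  tt <- seq(0, 64 - 1 / fs, by = 1 / fs)
  sig <- raw_signal(sin(2 * pi * 10 * tt), fs, "EEG")
  bp <- eeg_band_powers(sig, segment_windows(64))
  linear <- 10^(as.numeric(bp[1, c("delta", "theta", "alpha", "beta", "gamma")]) / 10)
  expect_gte(linear[3] / sum(linear), 0.95)

  zero <- eeg_band_powers(raw_signal(rep(0, length(tt)), fs, "EEG"),
                          segment_windows(64))
  expect_true(all(as.numeric(zero[1, -1]) == -120))
})

test_that("white-noise band powers are proportional to bandwidth", {
  fs <- 128
  set.seed(99)
  sig <- raw_signal(rnorm(fs * (64 + 99 * 5)), fs, "EEG")
  bp <- eeg_band_powers(sig, segment_windows(signal_duration(sig)))
  expect_equal(nrow(bp), 100)
  widths <- c(3, 3.5, 4, 17, 17.5)  # delta..gamma widths in Hz
  mean_lin <- vapply(c("delta", "theta", "alpha", "beta", "gamma"),
                     function(ch) mean(10^(bp[[ch]] / 10)), numeric(1))
  ratio <- mean_lin / widths
  expect_true(all(abs(ratio / mean(ratio) - 1) < 0.10))
})

test_that("the assembled feature matrix has 8 named channels on one grid", {
  f <- small_features()
  expect_s3_class(f, "noci_features")
  expect_equal(setdiff(names(f), "window_end_s"), feature_channels())
  expect_equal(nrow(f), floor((600 - 64) / 5) + 1)
  expect_equal(f$window_end_s[1], 64)
  expect_true(all(diff(f$window_end_s) == 5))
  expect_false(anyNA(as.matrix(f)))
})

test_that("feature matrices round-trip through CSV", {
  f <- small_features()
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(f, path)
  f2 <- read_features_csv(path)
  expect_equal(as.data.frame(f2), as.data.frame(f), tolerance = 1e-9)
})

test_that("features correlate with the latent trace with the coupled signs", {
  b <- small_session()
  f <- small_features()
  z <- approx(b$truth_noci$time_s, b$truth_noci$noci, xout = f$window_end_s,
              rule = 2)$y
  expect_gt(cor(f$delta, z), 0)
  expect_lt(cor(f$alpha, z), 0)
  expect_lt(cor(f$ppga, z), 0)
  expect_gt(cor(f$ppg_auc, z), 0)
})
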