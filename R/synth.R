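# Synthetic operating-room session generator.
#
# Downstream stages (feature extraction, normalization, model fitting,
# evaluation) are validated against sessions with known ground truth: a latent
# nociception trace stepped up at surgical events, and ECG/PPG/EEG channels
# whose relevant features are coupled to that trace with known signs --
# delta and gamma EEG power and the PPG waveform area rise with nociception,
# alpha power and the PPG pulse amplitude fall, and the high-frequency RR
# modulation is mildly suppressed (sympathetic activation / vagal withdrawal).

#' Specify a synthetic operating-room session
#'
#' Collects every knob of the simulator: signal rates, the surgical event
#' schedule (intubation `t1`, incision `t2`, extubation `t3`), the latent
#' nociception dynamics, the feature-to-nociception couplings and the rater
#' panel. Defaults describe a 30-minute case with three events and four raters
#' whose bias/spread match the magnitudes seen in expert panels (biases within
#' a few score points, pairwise difference SDs around 8).
#'
#' @param duration_s Session length, seconds (> 128).
#' @param ecg_rate,ppg_rate,eeg_rate Sampling rates in Hz.
#' @param events Data frame with columns `label` (`"t1"`,`"t2"`,`"t3"`) and
#'   `time_s`; all times must lie in `(64, duration_s - 64)`. Defaults to the
#'   three canonical events at 1/6, 1/2 and 5/6 of the session.
#' @param baseline_hr Baseline heart rate, beats/min (40--140).
#' @param hf_mod_freq Respiratory-band RR modulation frequency, Hz
#'   (within 0.15--0.5).
#' @param hf_rr_amp Fractional amplitude of the HF RR modulation (0 disables).
#' @param baseline_noci Latent nociception baseline on the 0--100 scale.
#' @param noci_step Rise of the latent trace per surgical event (score units).
#' @param noci_noise_sd SD of the slow stochastic drift added to the trace.
#' @param couplings Named list of signed feature couplings (fractional change
#'   of the feature per unit of standardized nociception): `delta`, `alpha`,
#'   `gamma`, `ppga`, `ppg_width`, `rrhf`.
#' @param rater_profiles Data frame with columns `bias` and `sd` (score units),
#'   one row per rater.
#' @param rater_stagger_s Maximum random offset of each rater's start/end
#'   (seconds); exercises the \[L, U\] synchronizer.
#' @param seed Integer seed; one seed fans out to per-channel substreams.
#' @return A `session_spec` list.
#' @export
session_spec <- function(duration_s = 1800,
                         ecg_rate = 512, ppg_rate = 128, eeg_rate = 128,
                         events = tibble(label = c("t1", "t2", "t3"),
                                         time_s = round(duration_s * c(1, 3, 5) / 6)),
                         baseline_hr = 70,
                         hf_mod_freq = 0.25,
                         hf_rr_amp = 0.05,
                         baseline_noci = 45,
                         noci_step = 15,
                         noci_noise_sd = 2,
                         couplings = list(delta = 0.6, alpha = -0.6, gamma = 0.5,
                                          ppga = -0.15, ppg_width = 0.7,
                                          rrhf = -0.3),
                         rater_profiles = tibble(bias = c(-2, -1, 2, 5),
                                                 sd = c(6, 6, 6, 6)),
                         rater_stagger_s = 30,
                         seed = 1L) {
  assert_scalar_number(duration_s, "duration_s", lower = 128 + 1e-9)
  assert_scalar_number(baseline_hr, "baseline_hr", lower = 40, upper = 140)
  assert_scalar_number(hf_mod_freq, "hf_mod_freq", lower = 0.15, upper = 0.5)
  assert_scalar_number(hf_rr_amp, "hf_rr_amp", lower = 0)
  assert_scalar_number(noci_step, "noci_step", lower = 0)
  events <- as_tibble(events)
  if (nrow(events) > 0) {
    stopifnot(all(c("label", "time_s") %in% names(events)))
    if (any(events$time_s <= 64 | events$time_s >= duration_s - 64)) {
      abort("All event times must lie in (64, duration_s - 64).")
    }
  }
  rater_profiles <- as_tibble(rater_profiles)
  if (any(rater_profiles$sd < 0)) abort("Rater `sd` must be >= 0.")
  structure(
    list(duration_s = duration_s, ecg_rate = ecg_rate, ppg_rate = ppg_rate,
         eeg_rate = eeg_rate, events = events, baseline_hr = baseline_hr,
         hf_mod_freq = hf_mod_freq, hf_rr_amp = hf_rr_amp,
         baseline_noci = baseline_noci, noci_step = noci_step,
         noci_noise_sd = noci_noise_sd, couplings = couplings,
         rater_profiles = rater_profiles, rater_stagger_s = rater_stagger_s,
         seed = as.integer(seed)),
    class = "session_spec"
  )
}

# Standardized nociception: maps the 0-100 scale to roughly [-1, 1] around
# mid-scale, the unit in which feature couplings are expressed.
noci_z <- function(value) (value - 50) / 50

# Event response kernel: linear rise over 30 s to the full step height, then
# exponential decay with a 300 s time constant -- a sustained but fading
# post-stimulus elevation.
event_kernel <- function(u, rise_s = 30, tau_s = 300) {
  k <- numeric(length(u))
  rising <- u >= 0 & u < rise_s
  decaying <- u >= rise_s
  k[rising] <- u[rising] / rise_s
  k[decaying] <- exp(-(u[decaying] - rise_s) / tau_s)
  k
}

#' Generate the latent nociception trace
#'
#' Baseline plus, for each surgical event, a smoothed step of height
#' `noci_step` (30 s linear rise, exponential decay with a 300 s time
#' constant), plus a slowly varying stochastic drift; clipped to \[0, 100\]
#' and sampled on the 5 s cadence.
#'
#' @param spec A [session_spec()].
#' @return Tibble with columns `time_s`, `noci`.
#' @export
gen_noci_trace <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  time_s <- seq(0, spec$duration_s, by = 5)
  value <- rep(spec$baseline_noci, length(time_s))
  for (i in seq_len(nrow(spec$events))) {
    value <- value + spec$noci_step * event_kernel(time_s - spec$events$time_s[i])
  }
  if (spec$noci_noise_sd > 0) {
    drift <- local_seed(substream(spec$seed, 1L), {
      # AR(1)-smoothed noise: slow wandering of the latent state.
      e <- rnorm(length(time_s))
      Reduce(function(prev, eps) 0.95 * prev + eps, e, accumulate = TRUE)
    })
    drift <- drift / sd(drift) * spec$noci_noise_sd
    value <- value + drift - mean(drift)
  }
  tibble(time_s = time_s, noci = pmin(100, pmax(0, value)))
}

# Beat times with HF (respiratory-band) RR modulation whose amplitude is
# scaled by the latent trace through the `rrhf` coupling.
gen_beat_times <- function(spec, trace) {
  rr0 <- 60 / spec$baseline_hr
  times <- numeric(ceiling(spec$duration_s / rr0 * 1.3) + 2L)
  times[1] <- 0.3
  n <- 1L
  while (times[n] + 2 * rr0 < spec$duration_s) {
    t_now <- times[n]
    z <- noci_z(interp_trace(trace$time_s, trace$noci, t_now))
    amp <- spec$hf_rr_amp * max(0, 1 + spec$couplings$rrhf * z)
    rr <- rr0 * (1 + amp * sin(2 * pi * spec$hf_mod_freq * t_now))
    n <- n + 1L
    times[n] <- t_now + rr
  }
  times[seq_len(n)]
}

# Place a template waveform (centered) at given times on a uniform grid.
place_template <- function(beat_times, template, rate, duration_s, amplitudes = NULL) {
  n <- round(duration_s * rate)
  x <- numeric(n)
  m <- length(template)
  half <- (m - 1L) %/% 2L
  if (is.null(amplitudes)) amplitudes <- rep(1, length(beat_times))
  centers <- round(beat_times * rate) + 1L
  for (k in seq_along(centers)) {
    i0 <- centers[k] - half
    i1 <- i0 + m - 1L
    lo <- max(1L, i0); hi <- min(n, i1)
    if (lo > hi) next
    x[lo:hi] <- x[lo:hi] + amplitudes[k] * template[(lo - i0 + 1L):(hi - i0 + 1L)]
  }
  x
}

#' Generate a synthetic ECG channel
#'
#' QRS-like Gaussian-derivative complexes at beat times whose RR intervals
#' carry a sinusoidal high-frequency modulation at `hf_mod_freq`; the
#' modulation amplitude is scaled by the latent trace. Exact R-peak times are
#' returned as ground truth.
#'
#' @param spec A [session_spec()].
#' @param trace Latent trace from [gen_noci_trace()].
#' @return List with `signal` (a `raw_signal`) and `r_times_s`.
#' @export
gen_ecg <- function(spec, trace) {
  stopifnot(inherits(spec, "session_spec"))
  r_times <- gen_beat_times(spec, trace)
  rate <- spec$ecg_rate
  # QRS template: sharp positive peak (Gaussian, sigma 12 ms) flanked by
  # Q/S dips (negative Gaussian derivative lobes); morphology is not used
  # downstream, only R timing.
  tt <- seq(-0.08, 0.08, by = 1 / rate)
  qrs <- exp(-tt^2 / (2 * 0.012^2)) - 0.25 * exp(-(tt - 0.03)^2 / (2 * 0.015^2)) -
    0.15 * exp(-(tt + 0.035)^2 / (2 * 0.02^2))
  x <- place_template(r_times, qrs, rate, spec$duration_s)
  noise <- local_seed(substream(spec$seed, 2L), rnorm(length(x), sd = 0.02))
  sig <- raw_signal(x + noise, rate = rate, kind = "ECG")
  list(signal = sig, r_times_s = r_times)
}

#' Generate a synthetic PPG channel
#'
#' A pulse train synchronous with the heart beat. Per-beat pulse amplitude is
#' negatively coupled to the latent trace (vasoconstriction under nociceptive
#' activation) while pulse width -- hence waveform area -- is positively
#' coupled, so the amplitude (PPGA) and area (PPG AUC) features are separable.
#'
#' @param spec A [session_spec()].
#' @param trace Latent trace from [gen_noci_trace()].
#' @param beat_times Optional beat times (seconds); defaults to the same beat
#'   process used for the ECG so the channels stay synchronous.
#' @param noise_sd Additive white-noise SD (0 gives a clean signal).
#' @return List with `signal` (a `raw_signal`) and `beats`, a tibble of
#'   ground-truth per-beat `time_s`, `amplitude` and `width_s`.
#' @export
gen_ppg <- function(spec, trace, beat_times = NULL, noise_sd = 0.01) {
  stopifnot(inherits(spec, "session_spec"))
  if (is.null(beat_times)) beat_times <- gen_beat_times(spec, trace)
  rate <- spec$ppg_rate
  z <- noci_z(interp_trace(trace$time_s, trace$noci, beat_times))
  amps <- pmax(0.05, 1 + spec$couplings$ppga * z)
  widths <- pmax(0.04, 0.12 * (1 + spec$couplings$ppg_width * z))
  n <- round(spec$duration_s * rate)
  x <- numeric(n)
  # Skewed pulse: fast systolic upstroke, slow diastolic runoff. Widths vary
  # per beat, so pulses are rendered beat-by-beat over a short support.
  support <- ceiling(0.9 * rate)
  grid <- (0:(support - 1L)) / rate
  idx0 <- round(beat_times * rate) + 1L
  for (k in seq_along(beat_times)) {
    u <- grid - 0.15
    w <- widths[k]
    pulse <- amps[k] * exp(-ifelse(u < 0, u^2 / (2 * (w / 2.5)^2), u^2 / (2 * w^2)))
    i0 <- idx0[k]
    i1 <- min(n, i0 + support - 1L)
    if (i0 >= 1L && i0 <= n) {
      span <- seq.int(i0, i1)
      x[span] <- x[span] + pulse[seq_along(span)]
    }
  }
  if (noise_sd > 0) {
    x <- x + local_seed(substream(spec$seed, 3L), rnorm(n, sd = noise_sd))
  }
  sig <- raw_signal(x, rate = rate, kind = "PPG")
  # The rendered peak sits ~0.15 s after the beat onset index.
  list(signal = sig,
       beats = tibble(time_s = beat_times + 0.15, amplitude = amps, width_s = widths))
}

eeg_band_table <- function() {
  tibble(band = c("delta", "theta", "alpha", "beta", "gamma"),
         lo = c(0.5, 4, 8, 13, 30.5),
         hi = c(3.5, 7.5, 12, 30, 48))
}

#' Generate a synthetic EEG channel
#'
#' Sum of five band-limited noise processes (delta, theta, alpha, beta,
#' gamma). Per-band instantaneous power follows the latent trace through the
#' configured couplings: delta and gamma power rise with nociception, alpha
#' power falls, theta and beta stay flat. Ground-truth per-window band powers
#' are returned on the 64 s / 5 s analysis grid.
#'
#' @param spec A [session_spec()].
#' @param trace Latent trace from [gen_noci_trace()].
#' @param base_powers Named baseline band variances (signal units squared).
#' @return List with `signal` (a `raw_signal`) and `band_truth`, a tibble of
#'   ground-truth band powers per analysis window.
#' @export
gen_eeg <- function(spec, trace,
                    base_powers = c(delta = 30, theta = 15, alpha = 20,
                                    beta = 8, gamma = 4)) {
  stopifnot(inherits(spec, "session_spec"))
  rate <- spec$eeg_rate
  n <- round(spec$duration_s * rate)
  t_samp <- (0:(n - 1L)) / rate
  z <- noci_z(interp_trace(trace$time_s, trace$noci, t_samp))
  coup <- c(delta = spec$couplings$delta, theta = 0, alpha = spec$couplings$alpha,
            beta = 0, gamma = spec$couplings$gamma)
  bands <- eeg_band_table()
  x <- numeric(n)
  power_fun <- list()
  for (i in seq_len(nrow(bands))) {
    b <- bands$band[i]
    if (base_powers[[b]] <= 0) next
    carrier <- local_seed(substream(spec$seed, 10L + i), rnorm(n))
    bf <- signal::butter(4, c(bands$lo[i], bands$hi[i]) / (rate / 2), type = "pass")
    carrier <- signal::filtfilt(bf, carrier)
    carrier <- carrier / sd(carrier)
    p_t <- base_powers[[b]] * pmax(0.05, 1 + coup[[b]] * z)
    x <- x + sqrt(p_t) * carrier
    power_fun[[b]] <- p_t
  }
  sig <- raw_signal(x, rate = rate, kind = "EEG")
  wins <- segment_windows(spec$duration_s)
  truth <- purrr::map_dfr(seq_len(nrow(wins)), function(k) {
    sel <- t_samp >= wins$start_s[k] & t_samp < wins$end_s[k]
    row <- purrr::map_dbl(bands$band, function(b) {
      if (is.null(power_fun[[b]])) 0 else mean(power_fun[[b]][sel])
    })
    names(row) <- bands$band
    c(list(window_end_s = wins$end_s[k]), as.list(row))
  })
  list(signal = sig, band_truth = as_tibble(truth))
}

#' Generate noisy rater assessments
#'
#' Each rater reports the latent trace plus a constant personal bias and
#' i.i.d. Gaussian noise, clipped to \[0, 100\], on the 5 s cadence. Rater
#' records are randomly truncated at both ends (up to `rater_stagger_s`) to
#' exercise the \[L, U\] synchronization step.
#'
#' @param spec A [session_spec()].
#' @param trace Latent trace from [gen_noci_trace()].
#' @return Tibble with columns `rater_id`, `time_s`, `score`.
#' @export
gen_raters <- function(spec, trace) {
  stopifnot(inherits(spec, "session_spec"))
  if (nrow(spec$rater_profiles) < 1) abort("At least one rater profile required.")
  local_seed(substream(spec$seed, 4L), {
    purrr::map_dfr(seq_len(nrow(spec$rater_profiles)), function(i) {
      prof <- spec$rater_profiles[i, ]
      start <- runif(1, 0, spec$rater_stagger_s)
      stop <- spec$duration_s - runif(1, 0, spec$rater_stagger_s)
      keep <- trace$time_s >= start & trace$time_s <= stop
      score <- trace$noci[keep] + prof$bias +
        if (prof$sd > 0) rnorm(sum(keep), sd = prof$sd) else 0
      tibble(rater_id = sprintf("R%02d", i),
             time_s = trace$time_s[keep],
             score = pmin(100, pmax(0, score)))
    })
  })
}

#' Simulate a full synthetic session
#'
#' Runs every generator under one seed and bundles the channels, the rater
#' panel, the event annotations and all ground truth (latent trace, R-peak
#' times, per-beat PPG amplitudes, per-window EEG band powers) into a
#' `session_bundle`.
#'
#' @param spec A [session_spec()].
#' @return A `session_bundle` list.
#' @export
simulate_session <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  trace <- gen_noci_trace(spec)
  ecg <- gen_ecg(spec, trace)
  ppg <- gen_ppg(spec, trace, beat_times = ecg$r_times_s)
  eeg <- gen_eeg(spec, trace)
  raters <- gen_raters(spec, trace)
  structure(
    list(spec = spec, ecg = ecg$signal, ppg = ppg$signal, eeg = eeg$signal,
         raters = raters, events = spec$events, truth_noci = trace,
         truth_r_times = ecg$r_times_s, truth_beats = ppg$beats,
         truth_band_powers = eeg$band_truth),
    class = "session_bundle"
  )
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle> %.0f s session, %d raters, %d events, seed %d\n",
              x$spec$duration_s, length(unique(x$raters$rater_id)),
              nrow(x$events), x$spec$seed))
  invisible(x)
}

#' Write a session bundle to a directory of plain-text files
#'
#' Signals as commented-header CSV, raters/events/truth as tidy CSV.
#'
#' @param bundle A `session_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(bundle, dir) {
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_signal_csv(bundle$ecg, file.path(dir, "ecg.csv"))
  write_signal_csv(bundle$ppg, file.path(dir, "ppg.csv"))
  write_signal_csv(bundle$eeg, file.path(dir, "eeg.csv"))
  write.csv(bundle$raters, file.path(dir, "raters.csv"), row.names = FALSE)
  write.csv(bundle$events, file.path(dir, "events.csv"), row.names = FALSE)
  write.csv(bundle$truth_noci, file.path(dir, "truth_noci.csv"), row.names = FALSE)
  invisible(dir)
}
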