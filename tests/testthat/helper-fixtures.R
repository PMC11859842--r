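# Shared fixtures, generated in code and cached per test run.

fixture_env <- new.env(parent = emptyenv())

# One moderate synthetic session (600 s, one incision-like event) reused by
# several feature tests.
small_session <- function() {
  if (is.null(fixture_env$small)) {
    spec <- session_spec(
      duration_s = 600,
      events = tibble::tibble(label = "t2", time_s = 300),
      seed = 101L
    )
    fixture_env$small <- simulate_session(spec)
  }
  fixture_env$small
}

small_features <- function() {
  if (is.null(fixture_env$small_feats)) {
    b <- small_session()
    fixture_env$small_feats <- suppressMessages(
      build_feature_matrix(b$ecg, b$ppg, b$eeg))
  }
  fixture_env$small_feats
}

# A clean sinusoidal pulse-train PPG for peak-detection tests.
pulse_train_ppg <- function(bpm = 60, duration_s = 60, rate = 128, amp = 1) {
  tt <- seq(0, duration_s - 1 / rate, by = 1 / rate)
  period <- 60 / bpm
  beats <- seq(0.5, duration_s - 0.5, by = period)
  x <- numeric(length(tt))
  for (b in beats) x <- x + amp * exp(-(tt - b)^2 / (2 * 0.05^2))
  list(signal = raw_signal(x, rate, "PPG"), beat_times = beats)
}

# Brute-force mid-rank empirical cdf used as the oracle for the histogram map.
brute_cdf <- function(x, pool) {
  vapply(x, function(v) (sum(pool < v) + 0.5 * sum(pool == v)) / length(pool),
         numeric(1))
}

# Exhaustive pair-counting AUC oracle.
brute_auc <- function(values, labels) {
  pos <- values[labels == 1]
  neg <- values[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Exhaustive Mann-Whitney U statistic (count of concordant pairs + half ties).
brute_u <- function(a, b) {
  total <- 0
  for (x in a) for (y in b) {
    total <- total + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  total
}
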