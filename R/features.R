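# Sliding-window feature extraction: raw ECG/PPG/EEG -> the 8-channel
# feature matrix (five EEG band powers, RRHF spectral power, PPGA, PPG AUC)
# on a 64 s window / 5 s step grid.

WINDOW_S <- 64
STEP_S <- 5
SUBSEG_S <- 16
KAISER_BETA <- 5
DB_FLOOR <- -120

#' Analysis window grid
#'
#' Windows of 64 s advanced in 5 s steps (consecutive windows overlap by
#' 59 s); a window is identified by its end time, and samples are indexed
#' half-open `[start, end)`.
#'
#' @param duration_s Available signal duration in seconds.
#' @param offset_s Start of the first window (default 0).
#' @return Tibble with columns `start_s`, `end_s`; zero rows (with a warning)
#'   if `duration_s < 64`.
#' @export
segment_windows <- function(duration_s, offset_s = 0) {
  if (duration_s < WINDOW_S) {
    warn("Signal shorter than one 64 s window; no windows emitted.")
    return(tibble(start_s = numeric(0), end_s = numeric(0)))
  }
  k <- 0:floor((duration_s - WINDOW_S) / STEP_S)
  tibble(start_s = offset_s + k * STEP_S, end_s = offset_s + k * STEP_S + WINDOW_S)
}

# Samples of a raw_signal falling in [start_s, end_s), 0-based times.
window_samples <- function(sig, start_s, end_s) {
  i0 <- floor((start_s - sig$start_s) * sig$rate) + 1L
  i1 <- floor((end_s - sig$start_s) * sig$rate)
  if (i0 < 1L || i1 > length(sig$samples)) return(NULL)
  sig$samples[i0:i1]
}

## ---- ECG: Pan-Tompkins R-peak detection ------------------------------------

#' Detect R peaks in an ECG channel
#'
#' Classical Pan-Tompkins stages: 5--15 Hz band-pass, derivative, squaring,
#' 150 ms moving-window integration, then adaptive dual thresholds (signal /
#' noise peak estimates) with search-back and a 200 ms refractory period.
#' Detected peaks are refined to the local maximum of the band-passed ECG.
#'
#' @param ecg A `raw_signal` of kind `"ECG"` (rate >= 100 Hz, >= 5 s).
#' @return Numeric vector of strictly increasing R-peak times (seconds);
#'   empty (with a warning) on flat input.
#' @export
detect_r_peaks <- function(ecg) {
  stopifnot(inherits(ecg, "raw_signal"), ecg$kind == "ECG")
  fs <- ecg$rate
  if (fs < 100) abort("ECG rate must be >= 100 Hz.")
  if (signal_duration(ecg) < 5) abort("ECG must be at least 5 s long.")
  x <- ecg$samples
  if (sd(x) < 1e-12) {
    warn("Flat ECG signal; no R peaks detected.")
    return(numeric(0))
  }
  bp <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x)
  dx <- c(0, diff(xf))
  sq <- dx^2
  mwi <- moving_average(sq, round(0.150 * fs))

  refractory <- round(0.200 * fs)
  # Candidate local maxima of the integrated signal.
  is_peak <- c(FALSE, diff(sign(diff(mwi))) < 0, FALSE)
  cand <- which(is_peak)
  if (length(cand) == 0) return(numeric(0))

  spki <- max(mwi[seq_len(min(length(mwi), round(2 * fs)))]) * 0.5
  npki <- mean(mwi[seq_len(min(length(mwi), round(2 * fs)))]) * 0.5
  thr1 <- npki + 0.25 * (spki - npki)
  peaks <- integer(0)
  last <- -Inf
  for (i in cand) {
    p <- mwi[i]
    if (i - last < refractory) next
    if (p > thr1) {
      peaks <- c(peaks, i)
      last <- i
      spki <- 0.125 * p + 0.875 * spki
    } else {
      npki <- 0.125 * p + 0.875 * npki
    }
    thr1 <- npki + 0.25 * (spki - npki)
    # Search-back: if a beat seems missed (gap > 1.66x median RR), accept the
    # best candidate above half threshold within the gap.
    if (length(peaks) > 8) {
      rrm <- median(diff(tail(peaks, 9)))
      if (i - last > 1.66 * rrm) {
        gap <- cand[cand > last + refractory & cand < i]
        if (length(gap)) {
          gbest <- gap[which.max(mwi[gap])]
          if (mwi[gbest] > 0.5 * thr1) {
            peaks <- sort(c(peaks, gbest))
            last <- max(peaks)
            spki <- 0.25 * mwi[gbest] + 0.75 * spki
          }
        }
      }
    }
  }
  if (length(peaks) == 0) return(numeric(0))
  # Refine each detection to the band-passed ECG maximum within +-100 ms.
  half <- round(0.100 * fs)
  refined <- vapply(peaks, function(i) {
    lo <- max(1L, i - half); hi <- min(length(xf), i + half)
    as.integer(lo + which.max(xf[lo:hi]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  refined <- refined[c(TRUE, diff(refined) >= refractory)]
  ecg$start_s + (refined - 1L) / fs
}

#' RR intervals from R-peak times
#'
#' @param r_times_s Strictly increasing R-peak times, seconds.
#' @return Tibble with `time_s` (time of the closing peak) and `rr_ms`.
#' @export
rr_from_peaks <- function(r_times_s) {
  if (length(r_times_s) < 2) abort("At least two R peaks required.")
  if (any(diff(r_times_s) <= 0)) abort("R-peak times must be strictly increasing.")
  tibble(time_s = r_times_s[-1], rr_ms = diff(r_times_s) * 1000)
}

## ---- RRHF: wavelet extraction of the 0.15-0.5 Hz RR component --------------

# Daubechies least-asymmetric 4-tap (D4) analysis filters.
d4_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))  # scaling (low-pass)
  g <- rev(h) * c(1, -1, 1, -1)                           # wavelet (high-pass)
  list(h = h, g = g)
}

# One periodized analysis step: x -> (approximation, detail), half length.
dwt_step <- function(x, h, g) {
  n <- length(x)
  xp <- c(x, x[seq_len(length(h) - 1L)])  # periodic extension
  a <- numeric(n %/% 2L)
  d <- numeric(n %/% 2L)
  for (k in seq_along(h)) {
    idx <- seq(k, by = 2L, length.out = n %/% 2L)
    a <- a + h[k] * xp[idx]
    d <- d + g[k] * xp[idx]
  }
  list(a = a, d = d)
}

# One periodized synthesis step: (a, d) -> signal of doubled length.
idwt_step <- function(a, d, h, g) {
  n2 <- 2L * length(a)
  up <- function(v) { out <- numeric(n2 + length(h) - 1L); out[seq(1, by = 2L, length.out = length(v))] <- v; out }
  ua <- up(a); ud <- up(d)
  y <- numeric(n2 + length(h) - 1L)
  for (k in seq_along(h)) {
    y[k:(k + n2 - 1L)] <- y[k:(k + n2 - 1L)] + h[k] * ua[seq_len(n2)] + g[k] * ud[seq_len(n2)]
  }
  # fold the periodic tail back
  tail_len <- length(h) - 1L
  y[seq_len(tail_len)] <- y[seq_len(tail_len)] + y[n2 + seq_len(tail_len)]
  y[seq_len(n2)]
}

# Periodized DWT to `levels` levels; returns details d1..dJ and approximation.
dwt_periodic <- function(x, levels) {
  f <- d4_filters()
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    st <- dwt_step(a, f$h, f$g)
    details[[j]] <- st$d
    a <- st$a
  }
  list(details = details, approx = a)
}

# Reconstruct the signal from a subset of detail levels (others zeroed);
# the final approximation is included only on request.
dwt_reconstruct <- function(decomp, keep_levels, n_out, include_approx = FALSE) {
  f <- d4_filters()
  levels <- length(decomp$details)
  a <- if (include_approx) decomp$approx else numeric(length(decomp$approx))
  for (j in rev(seq_len(levels))) {
    d <- if (j %in% keep_levels) decomp$details[[j]] else numeric(length(decomp$details[[j]]))
    a <- idwt_step(a, d, f$h, f$g)
  }
  a[seq_len(n_out)]
}

#' Extract the high-frequency RR component (RRHF)
#'
#' The unevenly sampled RR tachogram is cubic-interpolated onto a uniform
#' 4 Hz grid, decomposed with a periodized Daubechies D4 wavelet transform,
#' and reconstructed from the detail levels whose dyadic bands cover
#' 0.15--0.5 Hz (d3: 0.25--0.5 Hz, d4: 0.125--0.25 Hz at 4 Hz); residual
#' out-of-band leakage is removed with a zero-phase 0.15--0.5 Hz band-pass.
#'
#' @param rr Tibble from [rr_from_peaks()] spanning >= 64 s.
#' @param resample_hz Uniform tachogram rate (default 4 Hz, the HRV
#'   convention).
#' @param span_s Optional `c(start, end)` of the uniform grid; the tachogram
#'   is held flat beyond the first/last beat so edge analysis windows stay
#'   covered. Defaults to the RR series' own span.
#' @return Tibble with `time_s` and `rrhf_ms`.
#' @export
extract_rrhf <- function(rr, resample_hz = 4, span_s = NULL) {
  stopifnot(is.data.frame(rr), all(c("time_s", "rr_ms") %in% names(rr)))
  span <- diff(range(rr$time_s))
  if (span < WINDOW_S) abort("RR series must span at least 64 s.")
  span_s <- span_s %||% range(rr$time_s)
  t_out <- seq(span_s[1], span_s[2], by = 1 / resample_hz)
  inside <- t_out >= min(rr$time_s) & t_out <= max(rr$time_s)
  tach <- numeric(length(t_out))
  tach[inside] <- spline(rr$time_s, rr$rr_ms, xout = t_out[inside])$y
  tach[!inside] <- approx(rr$time_s, rr$rr_ms, xout = t_out[!inside], rule = 2)$y
  tach <- tach - mean(tach)
  # pad to a multiple of 2^levels for the periodized transform
  levels <- 4L
  n <- length(tach)
  n_pad <- ceiling(n / 2^levels) * 2^levels
  xp <- c(tach, rev(tach)[seq_len(n_pad - n)])
  dec <- dwt_periodic(xp, levels)
  hf <- dwt_reconstruct(dec, keep_levels = c(3L, 4L), n_out = n)
  bp <- signal::butter(4, c(0.15, 0.5) / (resample_hz / 2), type = "pass")
  hf <- signal::filtfilt(bp, hf)
  tibble(time_s = t_out, rrhf_ms = hf)
}

## ---- spectral power helpers ------------------------------------------------

# Mean power of a tapered segment restricted to [lo, hi] Hz via the
# periodogram: sum over one-sided in-band bins of 2|X_j|^2 / (N * sum(w^2)).
# With lo = 0, hi = Inf this equals the taper-weighted mean square (Parseval).
tapered_band_power <- function(x, fs, lo = 0, hi = Inf, beta = KAISER_BETA) {
  n <- length(x)
  w <- signal::kaiser(n, beta)
  X <- fft((x - mean(x)) * w)
  nyq <- floor(n / 2)
  j <- seq_len(nyq)                    # positive-frequency bins
  f <- j * fs / n
  scale <- ifelse(j < nyq | n %% 2L == 1L, 2, 1)  # Nyquist bin not doubled
  keep <- f >= lo & f <= hi
  sum(scale[keep] * Mod(X[j + 1L][keep])^2) / (n * sum(w^2))
}

to_db <- function(p) pmax(DB_FLOOR, 10 * log10(pmax(p, 10^(DB_FLOOR / 10))))

# Average of the four non-overlapping 16 s Kaiser-tapered subsegment powers
# for one 64 s window of a uniform series.
window_subseg_power <- function(x, fs, lo = 0, hi = Inf) {
  nsub <- round(SUBSEG_S * fs)
  k <- floor(length(x) / nsub)
  if (k < 1) return(NA_real_)
  mean(vapply(seq_len(min(k, WINDOW_S / SUBSEG_S)), function(i) {
    tapered_band_power(x[((i - 1L) * nsub + 1L):(i * nsub)], fs, lo, hi)
  }, numeric(1)))
}

#' RRHF spectral power per analysis window
#'
#' Each 64 s window of the uniform RRHF series is split into four 16 s
#' subsegments; each is Kaiser-tapered (beta = 5) and its in-band
#' (0.15--0.5 Hz) periodogram power computed; the four estimates are averaged
#' on the linear scale and reported in dB (floor -120 dB). Windows not fully
#' covered by the series are skipped.
#'
#' @param rrhf Tibble from [extract_rrhf()].
#' @param windows Window grid from [segment_windows()].
#' @return Tibble with `window_end_s`, `rrhf_ps` (dB).
#' @export
rrhf_power <- function(rrhf, windows) {
  stopifnot(all(c("time_s", "rrhf_ms") %in% names(rrhf)))
  fs <- 1 / median(diff(rrhf$time_s))
  purrr::map_dfr(seq_len(nrow(windows)), function(k) {
    sel <- rrhf$time_s >= windows$start_s[k] & rrhf$time_s < windows$end_s[k]
    x <- rrhf$rrhf_ms[sel]
    if (length(x) < round(WINDOW_S * fs) - 1) {
      return(tibble(window_end_s = numeric(0), rrhf_ps = numeric(0)))
    }
    tibble(window_end_s = windows$end_s[k],
           rrhf_ps = to_db(window_subseg_power(x, fs, lo = 0.15, hi = 0.5)))
  })
}

## ---- PPG -------------------------------------------------------------------

#' Band-pass filter a PPG channel
#'
#' Chebyshev type II fifth-order band-pass, 0.5--8 Hz, applied zero-phase
#' (forward-backward), removing DC and high-frequency noise. Implemented as a
#' high-pass/low-pass cascade for numerical stability at the low band edge.
#'
#' @param ppg A `raw_signal` of kind `"PPG"` (rate >= 16 Hz).
#' @return A filtered `raw_signal`.
#' @export
filter_ppg <- function(ppg) {
  stopifnot(inherits(ppg, "raw_signal"), ppg$kind == "PPG")
  fs <- ppg$rate
  if (fs < 16) abort("PPG rate must be at least 16 Hz (2 x 8 Hz cutoff).")
  hp <- signal::cheby2(5, 20, 0.5 / (fs / 2), type = "high")
  lp <- signal::cheby2(5, 20, 8 / (fs / 2), type = "low")
  y <- signal::filtfilt(lp, signal::filtfilt(hp, ppg$samples - mean(ppg$samples)))
  raw_signal(y, rate = fs, kind = "PPG", start_s = ppg$start_s)
}

#' Detect PPG pulse peaks (AMPD)
#'
#' Automatic multiscale-based peak detection: a point is a peak if it exceeds
#' both neighbours at every scale up to the scale that maximizes the global
#' count of scale-local maxima. Scales are capped at 2 s to bound memory.
#'
#' @param ppg A filtered PPG `raw_signal` (>= 10 s).
#' @param max_scale_s Maximum comparison lag, seconds.
#' @return Tibble with `time_s` and `amplitude` (empty on flat input).
#' @export
detect_ppg_peaks <- function(ppg, max_scale_s = 2) {
  stopifnot(inherits(ppg, "raw_signal"))
  if (signal_duration(ppg) < 10) abort("PPG must be at least 10 s long.")
  x <- ppg$samples
  n <- length(x)
  if (sd(x) < 1e-12) {
    return(tibble(time_s = numeric(0), amplitude = numeric(0)))
  }
  # remove the linear trend, as the original algorithm prescribes
  tt <- seq_len(n)
  x_d <- x - (stats::lm.fit(cbind(1, tt), x)$fitted.values)
  L <- min(ceiling(n / 2) - 1L, round(max_scale_s * ppg$rate))
  gamma <- numeric(L)
  for (k in seq_len(L)) {
    i <- (k + 1L):(n - k)
    gamma[k] <- sum(x_d[i] > x_d[i - k] & x_d[i] > x_d[i + k])
  }
  # scale with the most scale-local maxima; on ties prefer the largest scale,
  # which suppresses sub-beat ripples
  lambda <- max(which(gamma == max(gamma)))
  ok <- rep(TRUE, n)
  for (k in seq_len(lambda)) {
    i <- (k + 1L):(n - k)
    good <- rep(FALSE, n)
    good[i] <- x_d[i] > x_d[i - k] & x_d[i] > x_d[i + k]
    ok <- ok & good
  }
  idx <- which(ok)
  tibble(time_s = ppg$start_s + (idx - 1L) / ppg$rate, amplitude = x[idx])
}

#' PPG pulse-amplitude (PPGA) trend per analysis window
#'
#' The per-beat amplitude series is smoothed with a 16 s moving average (the
#' long-term trend matters more than beat-to-beat changes) and sampled at each
#' window end. Windows whose trailing 16 s contain no beat (a gap > 5 s in
#' practice) are linearly interpolated from neighbours and flagged.
#'
#' @param peaks Tibble from [detect_ppg_peaks()] (>= 2 peaks).
#' @param windows Window grid from [segment_windows()].
#' @return Tibble with `window_end_s`, `ppga`, `interpolated`.
#' @export
compute_ppga <- function(peaks, windows) {
  if (nrow(peaks) < 2) abort("At least two PPG peaks required.")
  vals <- vapply(seq_len(nrow(windows)), function(k) {
    t_end <- windows$end_s[k]
    sel <- peaks$time_s > t_end - SUBSEG_S & peaks$time_s <= t_end
    if (!any(sel)) NA_real_ else mean(peaks$amplitude[sel])
  }, numeric(1))
  flagged <- is.na(vals)
  if (any(flagged)) {
    if (all(flagged)) abort("No PPG beats fall inside any analysis window.")
    vals <- approx(windows$end_s[!flagged], vals[!flagged],
                   xout = windows$end_s, rule = 2)$y
    warn(sprintf("PPGA interpolated over %d window(s) with no beats.", sum(flagged)))
  }
  tibble(window_end_s = windows$end_s, ppga = vals, interpolated = flagged)
}

#' PPG area under the curve per analysis window
#'
#' Trapezoidal integral of the rectified (absolute) filtered PPG over each
#' fully covered 64 s window; rectification makes the value invariant to the
#' zero-mean of the band-passed waveform.
#'
#' @param ppg A filtered PPG `raw_signal`.
#' @param windows Window grid from [segment_windows()].
#' @return Tibble with `window_end_s`, `ppg_auc`.
#' @export
compute_ppg_auc <- function(ppg, windows) {
  stopifnot(inherits(ppg, "raw_signal"))
  purrr::map_dfr(seq_len(nrow(windows)), function(k) {
    x <- window_samples(ppg, windows$start_s[k], windows$end_s[k])
    if (is.null(x)) return(tibble(window_end_s = numeric(0), ppg_auc = numeric(0)))
    ax <- abs(x)
    auc <- (sum(ax) - (ax[1] + ax[length(ax)]) / 2) / ppg$rate
    tibble(window_end_s = windows$end_s[k], ppg_auc = auc)
  })
}

## ---- EEG -------------------------------------------------------------------

#' Band-limit an EEG channel to 0.5--48 Hz
#'
#' Zero-phase Butterworth high-pass (0.5 Hz, order 2) / low-pass (48 Hz,
#' order 6) cascade covering all five analysis bands.
#'
#' @param eeg A `raw_signal` of kind `"EEG"` (rate >= 96 Hz).
#' @return A filtered `raw_signal`.
#' @export
filter_eeg <- function(eeg) {
  stopifnot(inherits(eeg, "raw_signal"), eeg$kind == "EEG")
  fs <- eeg$rate
  if (fs < 96) abort("EEG rate must be at least 96 Hz.")
  hp <- signal::butter(2, 0.5 / (fs / 2), type = "high")
  lp <- signal::butter(6, 48 / (fs / 2), type = "low")
  y <- signal::filtfilt(lp, signal::filtfilt(hp, eeg$samples - mean(eeg$samples)))
  raw_signal(y, rate = fs, kind = "EEG", start_s = eeg$start_s)
}

#' EEG band powers per analysis window
#'
#' For each fully covered 64 s window, the five band powers (delta 0.5--3.5,
#' theta 4--7.5, alpha 8--12, beta 13--30, gamma 30.5--48 Hz) are estimated
#' as the average over four non-overlapping 16 s Kaiser-tapered (beta = 5)
#' subsegments of the in-band periodogram power, averaged on the linear scale
#' and reported in dB (floor -120 dB).
#'
#' @param eeg A filtered EEG `raw_signal`.
#' @param windows Window grid from [segment_windows()].
#' @return Tibble with `window_end_s` and one column per band.
#' @export
eeg_band_powers <- function(eeg, windows) {
  stopifnot(inherits(eeg, "raw_signal"))
  bands <- eeg_band_table()
  fs <- eeg$rate
  nsub <- round(SUBSEG_S * fs)
  w <- signal::kaiser(nsub, KAISER_BETA)
  nyq <- floor(nsub / 2)
  f_bins <- seq_len(nyq) * fs / nsub
  scale <- ifelse(seq_len(nyq) < nyq | nsub %% 2L == 1L, 2, 1)
  band_sel <- lapply(seq_len(nrow(bands)),
                     function(i) f_bins >= bands$lo[i] & f_bins <= bands$hi[i])
  purrr::map_dfr(seq_len(nrow(windows)), function(k) {
    x <- window_samples(eeg, windows$start_s[k], windows$end_s[k])
    if (is.null(x)) return(tibble(window_end_s = numeric(0)))
    # one periodogram per 16 s subsegment, shared across the five bands
    per_band <- matrix(0, WINDOW_S / SUBSEG_S, nrow(bands))
    for (i in seq_len(WINDOW_S / SUBSEG_S)) {
      seg <- x[((i - 1L) * nsub + 1L):(i * nsub)]
      X <- fft((seg - mean(seg)) * w)
      pxx <- scale * Mod(X[seq_len(nyq) + 1L])^2 / (nsub * sum(w^2))
      per_band[i, ] <- vapply(band_sel, function(s) sum(pxx[s]), numeric(1))
    }
    p <- to_db(colMeans(per_band))
    names(p) <- bands$band
    as_tibble(c(list(window_end_s = windows$end_s[k]), as.list(p)))
  })
}

## ---- assembly --------------------------------------------------------------

#' Build the 8-channel feature matrix
#'
#' Runs the full per-modality chain (R-peak detection, RRHF extraction and
#' power; PPG filtering, AMPD peaks, PPGA and AUC; EEG filtering and band
#' powers) on the common analysis-window grid and joins the channels by
#' window end time. Windows missing any channel are dropped with a message.
#'
#' @param ecg,ppg,eeg `raw_signal`s spanning a common interval >= 64 s.
#' @return A `noci_features` tibble: `window_end_s` plus channels `delta`,
#'   `theta`, `alpha`, `beta`, `gamma`, `rrhf_ps`, `ppga`, `ppg_auc`.
#' @export
build_feature_matrix <- function(ecg, ppg, eeg) {
  common_start <- max(ecg$start_s, ppg$start_s, eeg$start_s)
  common_end <- min(ecg$start_s + signal_duration(ecg),
                    ppg$start_s + signal_duration(ppg),
                    eeg$start_s + signal_duration(eeg))
  if (common_end - common_start < WINDOW_S) {
    abort("Signals share no common interval of at least 64 s.")
  }
  windows <- segment_windows(common_end - common_start, offset_s = common_start)

  r_times <- detect_r_peaks(ecg)
  rr <- rr_from_peaks(r_times)
  rrhf <- extract_rrhf(rr, span_s = c(common_start, common_end))
  f_rrhf <- rrhf_power(rrhf, windows)

  ppg_f <- filter_ppg(ppg)
  peaks <- detect_ppg_peaks(ppg_f)
  f_ppga <- compute_ppga(peaks, windows)[, c("window_end_s", "ppga")]
  f_auc <- compute_ppg_auc(ppg_f, windows)

  eeg_f <- filter_eeg(eeg)
  f_eeg <- eeg_band_powers(eeg_f, windows)

  out <- f_eeg |>
    dplyr::inner_join(f_rrhf, by = "window_end_s") |>
    dplyr::inner_join(f_ppga, by = "window_end_s") |>
    dplyr::inner_join(f_auc, by = "window_end_s")
  dropped <- nrow(windows) - nrow(out)
  if (dropped > 0) {
    inform(sprintf("Dropped %d window(s) with incomplete channel coverage.", dropped))
  }
  out <- out[, c("window_end_s", feature_channels())]
  class(out) <- c("noci_features", class(out))
  out
}

#' Names of the 8 feature channels
#' @return Character vector of channel names in canonical order.
#' @export
feature_channels <- function() {
  c("delta", "theta", "alpha", "beta", "gamma", "rrhf_ps", "ppga", "ppg_auc")
}

#' Write / read a feature matrix as CSV
#' @param features A `noci_features` tibble.
#' @param path File path.
#' @return The path (write) or a `noci_features` tibble (read).
#' @export
write_features_csv <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  out <- as_tibble(read.csv(path, check.names = FALSE))
  stopifnot(all(c("window_end_s", feature_channels()) %in% names(out)))
  out <- out[, c("window_end_s", feature_channels())]
  class(out) <- c("noci_features", class(out))
  out
}
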