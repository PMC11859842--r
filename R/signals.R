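# Raw physiological channels and their plain-text serialization.

#' Construct a raw physiological signal
#'
#' A `raw_signal` is a uniformly sampled single-channel recording: the sample
#' vector plus its kind (`"ECG"`, `"PPG"` or `"EEG"`), sampling rate in Hz and
#' start time in seconds. Signals are kept as plain numeric vectors rather than
#' long data frames because intraoperative channels run to millions of samples.
#'
#' @param samples Numeric vector of samples (no `NA`/`Inf`).
#' @param rate Sampling rate in Hz (> 0).
#' @param kind One of `"ECG"`, `"PPG"`, `"EEG"`.
#' @param start_s Start time of the first sample, seconds.
#' @return An object of class `raw_signal`.
#' @export
raw_signal <- function(samples, rate, kind = c("ECG", "PPG", "EEG"), start_s = 0) {
  kind <- match.arg(kind)
  assert_scalar_number(rate, "rate", lower = 1e-9)
  assert_scalar_number(start_s, "start_s")
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples))) {
    abort("`samples` must be finite and free of NA.")
  }
  structure(
    list(kind = kind, rate = rate, samples = samples, start_s = start_s),
    class = "raw_signal"
  )
}

#' @export
print.raw_signal <- function(x, ...) {
  cat(sprintf("<raw_signal> %s: %d samples @ %g Hz, %.1f s from t = %g s\n",
              x$kind, length(x$samples), x$rate,
              length(x$samples) / x$rate, x$start_s))
  invisible(x)
}

#' @export
length.raw_signal <- function(x) length(x$samples)

#' Signal duration in seconds
#' @param x A `raw_signal`.
#' @return Duration in seconds.
#' @export
signal_duration <- function(x) length(x$samples) / x$rate

# Sample times of a raw signal (seconds, first sample at start_s).
signal_times <- function(x) x$start_s + (seq_along(x$samples) - 1) / x$rate

#' Read / write a signal as columnar CSV
#'
#' The on-disk format is a CSV with a single `value` column preceded by
#' commented metadata lines (`# kind:`, `# rate_hz:`, `# start_s:`), so a
#' channel round-trips losslessly through plain text.
#'
#' @param x A `raw_signal`.
#' @param path File path.
#' @return `write_signal_csv()` returns `path` invisibly; `read_signal_csv()`
#'   returns a `raw_signal`.
#' @export
write_signal_csv <- function(x, path) {
  stopifnot(inherits(x, "raw_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# kind: %s", x$kind),
    sprintf("# rate_hz: %.10g", x$rate),
    sprintf("# start_s: %.10g", x$start_s),
    "value"
  ), con)
  writeLines(formatC(x$samples, format = "g", digits = 10), con)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  hdr <- readLines(path, n = 3L)
  meta <- function(key) sub(sprintf("^# %s: *", key), "", grep(key, hdr, value = TRUE)[1])
  values <- read.csv(path, comment.char = "#")$value
  raw_signal(values, rate = as.numeric(meta("rate_hz")),
             kind = meta("kind"), start_s = as.numeric(meta("start_s")))
}
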