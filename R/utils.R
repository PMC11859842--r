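# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, then restore the caller's RNG state.
# Every stochastic operation in the package routes through this so that one
# top-level seed fans out to reproducible substreams.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a per-component substream seed from a session seed. Kept well below
# .Machine$integer.max so seed arithmetic never overflows.
substream <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)))
  }
  invisible(x)
}

# Centered moving average over a fixed number of samples (box kernel),
# edge-padded so the output has the input's length.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  half <- (width - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  cs <- cumsum(xp)
  (cs[(width):length(xp)] - c(0, cs[seq_len(length(xp) - width)])) / width
}

# Linear interpolation of a (time, value) trace onto arbitrary times, with
# flat extrapolation beyond the ends.
interp_trace <- function(time_s, value, at) {
  approx(time_s, value, xout = at, method = "linear", rule = 2)$y
}

clip01 <- function(x) pmin(1, pmax(0, x))
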