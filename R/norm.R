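# Online and offline feature normalization blending group-population and
# accumulating per-patient statistics.
#
# At surgery start nothing is known about the patient, so each feature value
# is mapped through the group reference alone; as individual data accumulate
# the individual weight w ramps linearly from 0 to 0.7 over the first
# 10 minutes and stays there (group weight 1 - w). Three maps are supported:
# blended empirical cdfs (histogram), blended z-scores, and blended min-max.

#' Individual-data weight schedule
#'
#' `w = 0.7 * min(elapsed_s / 600, 1)`: the group transformation starts at
#' 100% weight and is reduced linearly until 10 minutes of individual data
#' have accumulated, after which the weights are fixed at 0.7 (individual) /
#' 0.3 (group).
#'
#' @param elapsed_s Seconds of individual data accumulated (vectorized, >= 0).
#' @return Individual weight(s) in \[0, 0.7\].
#' @export
weight_schedule <- function(elapsed_s) {
  if (any(elapsed_s < 0)) abort("`elapsed_s` must be non-negative.")
  0.7 * pmin(elapsed_s / 600, 1)
}

#' Build a group reference from training-split feature matrices
#'
#' Pools each channel across the supplied patients into a sorted sample pool
#' (empirical cdf support) with its min/max/mean/sd. Build it from training
#' patients only, so held-out evaluation stays leakage-free.
#'
#' @param feature_list List of `noci_features` tibbles (one per patient).
#' @param channels Channels to include (default all 8).
#' @return A `group_reference` object.
#' @export
group_reference <- function(feature_list, channels = feature_channels()) {
  if (is.data.frame(feature_list)) feature_list <- list(feature_list)
  pools <- purrr::map(channels, function(ch) {
    v <- sort(unlist(purrr::map(feature_list, function(f) f[[ch]])))
    v <- v[is.finite(v)]
    if (length(v) < 100) {
      abort(sprintf("Group reference for `%s` needs >= 100 samples, got %d.",
                    ch, length(v)))
    }
    if (sd(v) <= 0) abort(sprintf("Group reference for `%s` has zero spread.", ch))
    v
  })
  names(pools) <- channels
  structure(list(pools = pools, channels = channels), class = "group_reference")
}

#' @export
print.group_reference <- function(x, ...) {
  cat(sprintf("<group_reference> %d channels, %d samples each\n",
              length(x$channels), length(x$pools[[1]])))
  invisible(x)
}

#' Write / read a group reference as CSV
#' @param group A `group_reference`.
#' @param path File path.
#' @return The path (write) or a `group_reference` (read).
#' @export
write_group_csv <- function(group, path) {
  long <- purrr::map_dfr(group$channels, function(ch) {
    tibble(channel = ch, value = group$pools[[ch]])
  })
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_group_csv
#' @export
read_group_csv <- function(path) {
  long <- read.csv(path)
  channels <- unique(long$channel)
  pools <- purrr::map(channels, function(ch) sort(long$value[long$channel == ch]))
  names(pools) <- channels
  structure(list(pools = pools, channels = channels), class = "group_reference")
}

# Empirical cdf with the mid-rank convention,
# F(x) = (#{xi < x} + 0.5 * #{xi = x}) / n,
# linearly interpolated between order statistics and clamped to [0, 1]
# outside the pool range. `pool` must be sorted.
ecdf_midrank <- function(x, pool) {
  n <- length(pool)
  lt <- findInterval(x, pool, left.open = TRUE)   # #{xi < x} ... see below
  # findInterval(left.open=TRUE) counts xi <= x with strict handling reversed;
  # compute both counts explicitly:
  le <- findInterval(x, pool)                      # #{xi <= x}
  lt <- findInterval(x, pool, left.open = TRUE)    # #{xi < x}
  exact <- le > lt                                 # x equals a pool value
  f <- numeric(length(x))
  # exact matches: mid-rank
  f[exact] <- (lt[exact] + 0.5 * (le[exact] - lt[exact])) / n
  if (any(!exact)) {
    ux <- unique(pool)
    fu <- (findInterval(ux, pool, left.open = TRUE) +
             0.5 * (findInterval(ux, pool) - findInterval(ux, pool, left.open = TRUE))) / n
    f[!exact] <- approx(ux, fu, xout = x[!exact], rule = 1)$y
    below <- !exact & x < pool[1]
    above <- !exact & x > pool[n]
    f[below] <- 0
    f[above] <- 1
  }
  clip01(f)
}

#' Blended-cdf (histogram) normalization
#'
#' `X_norm = w * F_individual(x) + (1 - w) * F_group(x)`, each `F` the
#' mid-rank empirical cdf of its pool, output in \[0, 1\].
#'
#' @param x Value(s) to normalize.
#' @param individual Accumulated individual sample pool (may be empty).
#' @param group Group sample pool (sorted or not).
#' @param w Individual weight in \[0, 0.7\].
#' @return Normalized value(s) in \[0, 1\].
#' @export
normalize_histogram <- function(x, individual, group, w) {
  if (length(group) == 0) abort("Group reference pool is empty.")
  fg <- ecdf_midrank(x, sort(group))
  if (w > 0 && length(individual) == 0) {
    warn("Empty accumulated pool with w > 0; falling back to pure group cdf.")
    return(fg)
  }
  if (w == 0) return(fg)
  fi <- ecdf_midrank(x, sort(individual))
  clip01(w * fi + (1 - w) * fg)
}

#' Blended z-score normalization
#'
#' `X_norm = w * (x - mean_ind) / sd_ind + (1 - w) * (x - mean_grp) / sd_grp`.
#' A degenerate individual pool (sd = 0 or fewer than 2 samples) contributes 0
#' and is flagged with a warning.
#'
#' @inheritParams normalize_histogram
#' @return Normalized value(s), unbounded but finite.
#' @export
normalize_zscore <- function(x, individual, group, w) {
  sg <- sd(group)
  if (!is.finite(sg) || sg <= 0) abort("Group pool must have positive sd.")
  zg <- (x - mean(group)) / sg
  zi <- 0
  if (w > 0) {
    si <- if (length(individual) >= 2) sd(individual) else 0
    if (!is.finite(si) || si <= 0) {
      warn("Accumulated pool has zero spread; individual z-term set to 0.")
    } else {
      zi <- (x - mean(individual)) / si
    }
  }
  w * zi + (1 - w) * zg
}

#' Blended min-max normalization
#'
#' `X_norm = w * (x - min_ind) / (max_ind - min_ind) +
#'  (1 - w) * (x - min_grp) / (max_grp - min_grp)`, clipped to \[0, 1\]
#' (early-surgery values outside the group range would otherwise escape the
#' nominal range the downstream models were trained on). A degenerate
#' individual range contributes the mid-scale value 0.5, flagged.
#'
#' @inheritParams normalize_histogram
#' @return Normalized value(s) in \[0, 1\].
#' @export
normalize_minmax <- function(x, individual, group, w) {
  rg <- range(group)
  if (diff(rg) <= 0) abort("Group pool must have max > min.")
  mg <- (x - rg[1]) / diff(rg)
  mi <- 0.5
  if (w > 0) {
    ri <- if (length(individual)) range(individual) else c(0, 0)
    if (diff(ri) <= 0) {
      warn("Accumulated pool has max = min; individual min-max term set to 0.5.")
    } else {
      mi <- (x - ri[1]) / diff(ri)
    }
  }
  clip01(w * mi + (1 - w) * mg)
}

norm_fun <- function(method) {
  switch(method,
         histogram = normalize_histogram,
         zscore = normalize_zscore,
         minmax = normalize_minmax,
         abort(sprintf("Unknown normalization method `%s`.", method)))
}

#' Online normalization of a feature matrix
#'
#' Walks the analysis windows in time order. At each window the current value
#' is appended to the accumulated individual pool (current value inclusive),
#' the individual weight is taken from [weight_schedule()] with elapsed time
#' counted from the first window, and the blended map is applied.
#'
#' @param features A `noci_features` tibble (or any tibble with
#'   `window_end_s` plus the group's channels).
#' @param group A [group_reference()].
#' @param method `"histogram"`, `"zscore"` or `"minmax"`.
#' @return A tibble of the same shape with normalized channels; carries class
#'   `noci_features`.
#' @export
normalize_online <- function(features, group, method = c("minmax", "histogram", "zscore")) {
  method <- match.arg(method)
  fun <- norm_fun(method)
  stopifnot(inherits(group, "group_reference"))
  out <- features
  elapsed <- features$window_end_s - features$window_end_s[1]
  w <- weight_schedule(elapsed)
  for (ch in group$channels) {
    x <- features[[ch]]
    pool_g <- group$pools[[ch]]
    y <- numeric(length(x))
    for (i in seq_along(x)) {
      y[i] <- fun(x[i], individual = x[seq_len(i)], group = pool_g, w = w[i])
    }
    out[[ch]] <- y
  }
  out
}

#' Offline normalization of a feature matrix
#'
#' The reference ("perfect") normalization used to benchmark the online pass:
#' the individual pool is the complete series and the individual weight is
#' fixed at 0.7 (group 0.3).
#'
#' @inheritParams normalize_online
#' @return A tibble of the same shape with normalized channels.
#' @export
normalize_offline <- function(features, group, method = c("minmax", "histogram", "zscore")) {
  method <- match.arg(method)
  fun <- norm_fun(method)
  stopifnot(inherits(group, "group_reference"))
  out <- features
  for (ch in group$channels) {
    x <- features[[ch]]
    out[[ch]] <- fun(x, individual = x, group = group$pools[[ch]], w = 0.7)
  }
  out
}

#' Score normalization methods against the offline reference
#'
#' For each method, the full online pass is compared with the offline
#' (w = 0.7) reference by mean absolute error and Pearson correlation, pooled
#' across channels. Each metric is then min-max rescaled across the candidate
#' methods (MAE inverted so lower error scores higher) and the score is the
#' mean of the two rescaled metrics as a percentage:
#' `Score(%) = (Correlation_norm + MAE_norm) / 2 * 100`.
#'
#' @param features A `noci_features` tibble.
#' @param group A [group_reference()].
#' @param methods Candidate methods to compare.
#' @return Tibble with per-method `mae`, `correlation`, rescaled metrics and
#'   `score_pct`, sorted best-first.
#' @export
score_normalization_methods <- function(features, group,
                                        methods = c("histogram", "zscore", "minmax")) {
  res <- purrr::map_dfr(methods, function(m) {
    on <- normalize_online(features, group, m)
    off <- normalize_offline(features, group, m)
    x <- unlist(on[group$channels], use.names = FALSE)
    y <- unlist(off[group$channels], use.names = FALSE)
    if (sd(x) == 0 || sd(y) == 0) {
      inform(sprintf("Method `%s` produced a zero-variance series; excluded.", m))
      return(tibble(method = m, mae = NA_real_, correlation = NA_real_))
    }
    tibble(method = m, mae = mean(abs(x - y)), correlation = cor(x, y))
  })
  ok <- !is.na(res$mae)
  rescale <- function(v, invert = FALSE) {
    r <- range(v, na.rm = TRUE)
    s <- if (diff(r) == 0) rep(1, length(v)) else (v - r[1]) / diff(r)
    if (invert) 1 - s else s
  }
  res$mae_norm <- NA_real_
  res$corr_norm <- NA_real_
  res$mae_norm[ok] <- rescale(res$mae[ok], invert = TRUE)
  res$corr_norm[ok] <- rescale(res$correlation[ok])
  res$score_pct <- (res$mae_norm + res$corr_norm) / 2 * 100
  dplyr::arrange(res, dplyr::desc(.data$score_pct))
}

#' Combine two pre-rescaled metrics into a method score
#'
#' @param correlation_norm,mae_norm Metrics already rescaled to \[0, 1\].
#' @return Score in percent.
#' @export
normalization_score <- function(correlation_norm, mae_norm) {
  (correlation_norm + mae_norm) / 2 * 100
}
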