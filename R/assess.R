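# Multi-rater nociception assessments: synchronization to a common interval,
# inter-rater agreement statistics, and the consensus target.

#' Synchronize rater traces to a common interval
#'
#' Finds the latest start `L` and earliest end `U` across raters, drops
#' samples outside `[L, U]` and resamples every rater onto one 5 s grid by
#' previous-value (step) interpolation -- assessments are event-anchored
#' annotations, not continuous measurements.
#'
#' @param raters Tibble with columns `rater_id`, `time_s`, `score`
#'   (>= 2 raters).
#' @return List with `L`, `U` and `traces` (a tibble on the common grid).
#' @export
synchronize <- function(raters) {
  stopifnot(all(c("rater_id", "time_s", "score") %in% names(raters)))
  ids <- unique(raters$rater_id)
  if (length(ids) < 2) abort("At least two rater traces required.")
  spans <- raters |>
    dplyr::group_by(.data$rater_id) |>
    dplyr::summarise(start = min(.data$time_s), end = max(.data$time_s))
  L <- max(spans$start)
  U <- min(spans$end)
  if (U <= L) abort("Disjoint assessments: no common interval across raters.")
  grid <- seq(ceiling(L / STEP_S) * STEP_S, floor(U / STEP_S) * STEP_S, by = STEP_S)
  traces <- purrr::map_dfr(ids, function(id) {
    r <- raters[raters$rater_id == id, ]
    r <- r[order(r$time_s), ]
    tibble(rater_id = id, time_s = grid,
           score = approx(r$time_s, r$score, xout = grid,
                          method = "constant", f = 0, rule = 2)$y)
  })
  list(L = L, U = U, traces = traces)
}

# Wide subjects-x-raters matrix from a synchronized trace tibble.
traces_wide <- function(traces) {
  wide <- tidyr::pivot_wider(traces, names_from = "rater_id", values_from = "score")
  as.matrix(wide[, setdiff(names(wide), "time_s")])
}

#' Screen raters for systematic disagreement
#'
#' One-way ANOVA of score by rater across the synchronized grid, followed by
#' a per-rater post-hoc test (each rater against the others pooled,
#' Holm-adjusted, alpha = 0.05). Raters flagged here are candidates for
#' exclusion; dropping them is an explicit choice (see [consensus()]), never
#' automatic, preserving auditability.
#'
#' @param traces Synchronized trace tibble from [synchronize()].
#' @param alpha Significance level (default 0.05).
#' @return List with `anova` (one-row tibble: `f_statistic`, `p_value`) and
#'   `raters` (per-rater mean, p-value and `flagged`).
#' @export
anova_screen <- function(traces, alpha = 0.05) {
  ids <- unique(traces$rater_id)
  if (length(ids) < 3) {
    warn("Fewer than 3 raters; ANOVA screen skipped.")
    return(list(anova = tibble(f_statistic = NA_real_, p_value = NA_real_),
                raters = tibble(rater_id = ids,
                                mean = vapply(ids, function(i) mean(traces$score[traces$rater_id == i]), numeric(1)),
                                p_value = NA_real_, flagged = FALSE)))
  }
  fit <- aov(score ~ factor(rater_id), data = traces)
  tab <- anova(fit)
  per <- purrr::map_dfr(ids, function(id) {
    own <- traces$score[traces$rater_id == id]
    rest <- traces$score[traces$rater_id != id]
    tt <- t.test(own, rest)
    tibble(rater_id = id, mean = mean(own), p_value = tt$p.value)
  })
  per$p_value <- stats::p.adjust(per$p_value, method = "holm")
  per$flagged <- per$p_value < alpha
  list(anova = tibble(f_statistic = tab$`F value`[1], p_value = tab$`Pr(>F)`[1]),
       raters = per)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC with an
#' F-based 95% confidence interval (McGraw-Wong A,1): time points are
#' subjects, raters a random panel scoring every subject.
#'
#' @param traces Synchronized trace tibble from [synchronize()]
#'   (>= 2 raters, >= 10 common time points).
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with `icc`, `lower`, `upper`, `n_subjects`, `n_raters`.
#' @export
icc_agreement <- function(traces, conf_level = 0.95) {
  m <- traces_wide(traces)
  n <- nrow(m)
  k <- ncol(m)
  if (k < 2) abort("ICC requires at least two raters.")
  if (n < 10) abort("ICC requires at least 10 common time points.")
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (denom <= 0) {
    warn("Zero between-subject variance; ICC undefined.")
    return(tibble(icc = NA_real_, lower = NA_real_, upper = NA_real_,
                  n_subjects = n, n_raters = k))
  }
  icc <- (msr - mse) / denom
  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    lower <- upper <- icc
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - fl * mse) / (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) / (k * msc + (k * n - k - n) * mse + n * fu * msr)
  }
  tibble(icc = icc, lower = lower, upper = upper, n_subjects = n, n_raters = k)
}

#' Bland-Altman agreement between two paired series
#'
#' Bias = `mean(a - b)`, SD of the differences, 95% limits of agreement
#' `bias +/- 1.96 * SD`, and the percentage of pairs falling within the
#' limits.
#'
#' @param a,b Equal-length paired numeric series (n >= 3).
#' @return One-row tibble: `bias`, `sd`, `loa_lower`, `loa_upper`,
#'   `pct_within`, `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  if (length(a) < 3) abort("Bland-Altman requires at least 3 pairs.")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  lo <- bias - 1.96 * s
  hi <- bias + 1.96 * s
  tibble(bias = bias, sd = s, loa_lower = lo, loa_upper = hi,
         pct_within = 100 * mean(d >= lo & d <= hi), n = length(d))
}

#' Consensus nociception assessment
#'
#' Pointwise mean across the retained raters on the common grid.
#'
#' @param traces Synchronized trace tibble from [synchronize()].
#' @param keep Rater ids to retain (default all).
#' @return Tibble with `time_s`, `score`.
#' @export
consensus <- function(traces, keep = NULL) {
  if (!is.null(keep)) {
    traces <- traces[traces$rater_id %in% keep, ]
    if (nrow(traces) == 0) abort("No raters retained.")
  }
  traces |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(score = mean(.data$score)) |>
    dplyr::arrange(.data$time_s)
}

#' Full inter-rater agreement report
#'
#' Synchronizes the panel, runs the ANOVA screen, ICC(2,1) and all pairwise
#' Bland-Altman comparisons.
#'
#' @param raters Tibble with `rater_id`, `time_s`, `score`.
#' @param drop_flagged If `TRUE`, flagged raters are excluded from the
#'   consensus (explicit opt-in; default `FALSE`).
#' @return A `noci_agreement` list: `L`, `U`, `anova`, `raters`, `icc`,
#'   `pairwise` (Bland-Altman table with `group1`/`group2`), `consensus`.
#' @export
agreement_report <- function(raters, drop_flagged = FALSE) {
  sync <- synchronize(raters)
  screen <- anova_screen(sync$traces)
  icc <- icc_agreement(sync$traces)
  ids <- unique(sync$traces$rater_id)
  m <- traces_wide(sync$traces)
  pairs <- utils::combn(seq_along(ids), 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    dplyr::bind_cols(tibble(group1 = ids[i1], group2 = ids[i2]),
                     bland_altman(m[, i1], m[, i2]))
  })
  keep <- if (drop_flagged) screen$raters$rater_id[!screen$raters$flagged] else ids
  structure(
    list(L = sync$L, U = sync$U, traces = sync$traces, anova = screen$anova,
         raters = screen$raters, icc = icc, pairwise = pairwise,
         consensus = consensus(sync$traces, keep = keep), kept = keep),
    class = "noci_agreement"
  )
}

#' @export
print.noci_agreement <- function(x, ...) {
  cat(sprintf("<noci_agreement> [L, U] = [%.0f, %.0f] s, %d raters (%d kept)\n",
              x$L, x$U, nrow(x$raters), length(x$kept)))
  cat(sprintf("  ICC(2,1) = %.3f [%.3f, %.3f]\n", x$icc$icc, x$icc$lower, x$icc$upper))
  invisible(x)
}
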