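# ggplot2 views of the pipeline's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_abline geom_errorbar facet_wrap labs theme_minimal
NULL

#' Plot a feature matrix
#'
#' One panel per feature channel over window end time.
#'
#' @param object A `noci_features` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot noci_features
#' @export
autoplot.noci_features <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), dplyr::all_of(feature_channels()),
                              names_to = "channel", values_to = "value")
  ggplot(long, aes(x = .data$window_end_s, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~channel, scales = "free_y", ncol = 2) +
    labs(x = "window end (s)", y = NULL, title = "Feature channels") +
    theme_minimal()
}

#' Plot a model's training history
#'
#' @param object A `noci_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot noci_model
#' @export
autoplot.noci_model <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$epoch, y = .data$loss, linetype = .data$phase)) +
    geom_line() +
    labs(x = "epoch", y = "MSE (scaled target)",
         title = sprintf("%s training", toupper(object$kind))) +
    theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A `noci_roc` from [roc_at_events()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot noci_roc
#' @export
autoplot.noci_roc <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    geom_line() +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("ROC at surgical events (AUC = %.2f)", object$auc)) +
    theme_minimal()
}

#' Bland-Altman plot for two rater series
#'
#' Differences against pair means with the bias line and 95% limits of
#' agreement.
#'
#' @param a,b Equal-length paired series.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(a, b) {
  ba <- bland_altman(a, b)
  df <- tibble(mean = (a + b) / 2, diff = a - b)
  ggplot(df, aes(x = .data$mean, y = .data$diff)) +
    geom_point(alpha = 0.4, size = 0.8) +
    geom_hline(yintercept = ba$bias, colour = "blue") +
    geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
               colour = "red", linetype = "dashed") +
    geom_hline(yintercept = 0, colour = "darkgreen", linetype = "dotted") +
    labs(x = "pair mean", y = "difference",
         title = sprintf("Bland-Altman: bias %.2f, SD %.2f", ba$bias, ba$sd)) +
    theme_minimal()
}

#' Plot event responses
#'
#' Mean difference per event with standard-error bars.
#'
#' @param events_tbl Tibble from [event_response()].
#' @return A ggplot object.
#' @export
plot_event_response <- function(events_tbl) {
  ggplot(events_tbl, aes(x = .data$label, y = .data$difference)) +
    geom_point(size = 2) +
    geom_errorbar(aes(ymin = .data$difference - .data$se,
                      ymax = .data$difference + .data$se), width = 0.15) +
    geom_hline(yintercept = 0, linetype = "dotted") +
    labs(x = "surgical event", y = "mean after - mean before",
         title = "Event response") +
    theme_minimal()
}
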