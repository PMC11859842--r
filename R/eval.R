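# Evaluation battery: regression metrics, surgical-event response analysis,
# per-patient ROC discrimination of noxious stimuli, and the end-to-end
# pipeline runner.

#' Regression metrics between a prediction and its target
#'
#' @param pred,target Equal-length aligned numeric vectors.
#' @return One-row tibble: `mae`, `mse`, `pearson_r`, `r_squared`. With a
#'   zero-variance target the correlation-based metrics are `NA` (reported,
#'   not an error).
#' @export
regression_metrics <- function(pred, target) {
  if (length(pred) != length(target)) abort("`pred` and `target` lengths differ.")
  mae <- mean(abs(pred - target))
  mse <- mean((pred - target)^2)
  if (sd(target) == 0 || sd(pred) == 0) {
    inform("Zero-variance series; correlation and R-squared undefined.")
    r <- NA_real_
    r2 <- if (sd(target) == 0) NA_real_ else 1 - sum((target - pred)^2) / sum((target - mean(target))^2)
  } else {
    r <- cor(pred, target)
    r2 <- 1 - sum((target - pred)^2) / sum((target - mean(target))^2)
  }
  tibble(mae = mae, mse = mse, pearson_r = r, r_squared = r2)
}

# Pre/post samples around one event, excluding a guard gap of one window
# around the instant itself.
event_sides <- function(trace, event_time, span_s, guard_s) {
  pre <- trace$value[trace$time_s >= event_time - span_s & trace$time_s < event_time - guard_s]
  post <- trace$value[trace$time_s > event_time + guard_s & trace$time_s <= event_time + span_s]
  list(pre = pre, post = post)
}

#' Event-response analysis
#'
#' For each surgical event, compares the prediction over the `span_s` seconds
#' before and after (a 5 s guard gap around the instant is excluded from both
#' sides): difference of means, its standard error, and a two-sided
#' Mann-Whitney U test. Events with fewer than 5 points on either side are
#' skipped with a warning.
#'
#' @param trace Tibble with `time_s` and `value` (a prediction or NOA trace).
#' @param events Tibble with `label`, `time_s`.
#' @param span_s Window on each side of the event, seconds (default 180).
#' @param guard_s Guard gap excluded around the event instant (default 5).
#' @return Tibble with one row per analysed event: means before/after,
#'   `difference`, `se`, `p_value`, sample sizes.
#' @export
event_response <- function(trace, events, span_s = 180, guard_s = 5) {
  stopifnot(all(c("time_s", "value") %in% names(trace)),
            all(c("label", "time_s") %in% names(events)))
  purrr::map_dfr(seq_len(nrow(events)), function(i) {
    sides <- event_sides(trace, events$time_s[i], span_s, guard_s)
    if (length(sides$pre) < 5 || length(sides$post) < 5) {
      warn(sprintf("Event %s skipped: fewer than 5 points on one side.",
                   events$label[i]))
      return(tibble())
    }
    p <- suppressWarnings(
      wilcox.test(sides$post, sides$pre, alternative = "two.sided")$p.value)
    if (!is.finite(p)) p <- 1  # fully tied samples carry no evidence
    tibble(label = events$label[i], event_time_s = events$time_s[i],
           mean_before = mean(sides$pre), mean_after = mean(sides$post),
           difference = mean(sides$post) - mean(sides$pre),
           se = sqrt(var(sides$pre) / length(sides$pre) +
                       var(sides$post) / length(sides$post)),
           p_value = min(1, p),
           n_before = length(sides$pre), n_after = length(sides$post))
  })
}

# Rank-statistic AUC with mid-rank tie handling: the fraction of
# (positive, negative) pairs ordered correctly, counting ties as 1/2.
auc_rank <- function(values, labels) {
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(values, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC discrimination of noxious events
#'
#' Labels prediction points in the `span_s` seconds before each event 0 and
#' after each event 1 (guard gap excluded), pools the labelled points across
#' the patient's events, and computes the ROC curve and its AUC via the rank
#' statistic (mid-rank ties).
#'
#' @inheritParams event_response
#' @return A `noci_roc` list: `auc`, `curve` (tibble of `fpr`, `tpr`,
#'   monotone non-decreasing), `n_pos`, `n_neg`; `auc` is `NA` when only one
#'   class is present.
#' @export
roc_at_events <- function(trace, events, span_s = 180, guard_s = 5) {
  values <- numeric(0)
  labels <- integer(0)
  for (i in seq_len(nrow(events))) {
    sides <- event_sides(trace, events$time_s[i], span_s, guard_s)
    values <- c(values, sides$pre, sides$post)
    labels <- c(labels, rep(0L, length(sides$pre)), rep(1L, length(sides$post)))
  }
  auc <- auc_rank(values, labels)
  if (is.na(auc)) {
    warn("Single-class labels; AUC undefined.")
    curve <- tibble(fpr = c(0, 1), tpr = c(0, 1))
  } else {
    thr <- c(Inf, sort(unique(values), decreasing = TRUE))
    curve <- purrr::map_dfr(thr, function(s) {
      tibble(fpr = mean(values[labels == 0] >= s),
             tpr = mean(values[labels == 1] >= s))
    })
  }
  structure(list(auc = auc, curve = curve,
                 n_pos = sum(labels == 1), n_neg = sum(labels == 0)),
            class = "noci_roc")
}

#' @export
print.noci_roc <- function(x, ...) {
  cat(sprintf("<noci_roc> AUC = %.3f (%d pre / %d post points)\n",
              x$auc, x$n_neg, x$n_pos))
  invisible(x)
}

## ---- end-to-end pipeline ----------------------------------------------------

#' Pipeline configuration
#'
#' Study conditions for a full synthetic run: patient counts, session length,
#' normalization method, model kinds and the evaluation window.
#'
#' @param n_train,n_test Patients in the training and held-out splits.
#' @param duration_s Session length per patient, seconds.
#' @param method Normalization method for model inputs.
#' @param kinds Model kinds to train.
#' @param span_s Event-analysis window, seconds.
#' @param epochs Training epochs (defaults to the models' 50).
#' @param seed Master seed; patient sessions, splits and training fan out
#'   from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_train = 20, n_test = 5, duration_s = 1800,
                            method = "minmax", kinds = c("mlp", "lstm"),
                            span_s = 180, epochs = 50, seed = 1L) {
  structure(list(n_train = n_train, n_test = n_test, duration_s = duration_s,
                 method = method, kinds = kinds, span_s = span_s,
                 epochs = epochs, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Session spec for patient i of a pipeline run: event times jittered around
# the canonical intubation/incision/extubation schedule, scaled to duration.
patient_spec <- function(config, i) {
  base_events <- c(t1 = 1 / 6, t2 = 1 / 2, t3 = 5 / 6) * config$duration_s
  jitter <- local_seed(substream(config$seed, 100L + i), runif(3, -30, 30))
  hr <- local_seed(substream(config$seed, 200L + i), runif(1, 55, 90))
  session_spec(
    duration_s = config$duration_s,
    events = tibble(label = c("t1", "t2", "t3"),
                    time_s = pmin(pmax(base_events + jitter, 70),
                                  config$duration_s - 70)),
    baseline_hr = hr,
    seed = substream(config$seed, i)
  )
}

# Extract, then attach the aligned consensus target and latent truth.
process_patient <- function(bundle) {
  feats <- suppressMessages(
    build_feature_matrix(bundle$ecg, bundle$ppg, bundle$eeg))
  agree <- agreement_report(bundle$raters)
  list(features = feats, consensus = agree$consensus, agreement = agree,
       truth = bundle$truth_noci, events = bundle$events)
}

#' Run the full pipeline on synthetic sessions
#'
#' Simulate -> extract -> normalize (online, group reference built from the
#' training split only) -> train -> predict -> evaluate. Held-out patients
#' are scored against the latent generating trace with regression metrics,
#' event-response analysis and per-patient ROC.
#'
#' @param config A [pipeline_config()].
#' @param progress Emit per-stage messages.
#' @return A `noci_report` list: `models`, per-patient `regression`, `events`,
#'   `roc` tibbles, per-model summary in `summary`, and the config.
#' @export
run_pipeline <- function(config = pipeline_config(), progress = interactive()) {
  say <- function(...) if (progress) inform(sprintf(...))
  n_all <- config$n_train + config$n_test
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }
  say("Simulating %d synthetic sessions (%.0f s each)...", n_all, config$duration_s)
  patients <- stage("simulate+extract", lapply(seq_len(n_all), function(i) {
    p <- process_patient(simulate_session(patient_spec(config, i)))
    say("  patient %d/%d extracted (%d windows)", i, n_all, nrow(p$features))
    p
  }))
  train_idx <- seq_len(config$n_train)
  test_idx <- config$n_train + seq_len(config$n_test)

  say("Building group reference from %d training patients...", config$n_train)
  group <- stage("group_reference",
                 group_reference(lapply(patients[train_idx], `[[`, "features")))
  norm_feats <- stage("normalize", lapply(patients, function(p) {
    suppressWarnings(normalize_online(p$features, group, config$method))
  }))

  models <- list()
  report_rows <- list(regression = list(), events = list(), roc = list())
  for (kind in config$kinds) {
    say("Training %s...", toupper(kind))
    cfg <- model_config(kind, epochs = config$epochs, seed = substream(config$seed, 900L))
    ds_train <- bind_datasets(lapply(train_idx, function(i) {
      make_dataset(norm_feats[[i]], patients[[i]]$consensus, kind, cfg$seq_len)
    }))
    ds_val <- bind_datasets(lapply(test_idx, function(i) {
      make_dataset(norm_feats[[i]], patients[[i]]$consensus, kind, cfg$seq_len)
    }))
    fit <- stage(paste0("train_", kind), train_model(cfg, ds_train, ds_val))
    models[[kind]] <- fit
    for (i in test_idx) {
      pred <- predict(fit, norm_feats[[i]])
      truth <- patients[[i]]$truth
      target <- interp_trace(truth$time_s, truth$noci, pred$window_end_s)
      reg <- regression_metrics(pred$prediction, target)
      trace <- tibble(time_s = pred$window_end_s, value = pred$prediction)
      ev <- event_response(trace, patients[[i]]$events, span_s = config$span_s)
      roc <- roc_at_events(trace, patients[[i]]$events, span_s = config$span_s)
      pid <- sprintf("P%02d", i)
      report_rows$regression[[paste(kind, pid)]] <-
        dplyr::bind_cols(tibble(model = kind, patient = pid), reg,
                         tibble(pred_variance = var(pred$prediction)))
      report_rows$events[[paste(kind, pid)]] <-
        dplyr::bind_cols(tibble(model = kind, patient = pid), ev)
      report_rows$roc[[paste(kind, pid)]] <-
        tibble(model = kind, patient = pid, auc = roc$auc)
    }
  }
  regression <- dplyr::bind_rows(report_rows$regression)
  events <- dplyr::bind_rows(report_rows$events)
  roc <- dplyr::bind_rows(report_rows$roc)
  summary <- regression |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(mean_pearson = mean(.data$pearson_r),
                     mean_mae = mean(.data$mae),
                     mean_pred_variance = mean(.data$pred_variance)) |>
    dplyr::left_join(
      roc |> dplyr::group_by(.data$model) |>
        dplyr::summarise(mean_auc = mean(.data$auc, na.rm = TRUE)),
      by = "model")
  structure(
    list(config = config, models = models, group = group,
         regression = regression, events = events, roc = roc,
         summary = summary),
    class = "noci_report"
  )
}

#' @export
print.noci_report <- function(x, ...) {
  cat(sprintf("<noci_report> %d train / %d test patients, method = %s\n",
              x$config$n_train, x$config$n_test, x$config$method))
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Write a pipeline report to JSON and CSV
#'
#' @param report A `noci_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$regression, file.path(dir, "regression.csv"), row.names = FALSE)
  write.csv(report$events, file.path(dir, "events.csv"), row.names = FALSE)
  write.csv(report$roc, file.path(dir, "roc.csv"), row.names = FALSE)
  payload <- list(
    config = unclass(report$config),
    summary = report$summary,
    regression = report$regression,
    events = report$events,
    roc = report$roc
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
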