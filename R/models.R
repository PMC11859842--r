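# Nociception regressors: a multilayer perceptron and a stacked LSTM, both
# trained with Adam on mean-squared error against the expert consensus score
# scaled to [0, 1]. The networks and backpropagation are authored in base-R
# matrix code; gradients are finite-difference-checked in the test suite.

#' Model configuration
#'
#' Defaults are the pipeline's fixed operating point: MLP with hidden layers
#' 50/30 (ReLU), batch 125, learning rate 0.001; LSTM with hidden layers
#' 100/200 (sigmoid gates, tanh state), batch 256, learning rate 0.0001,
#' sequence length 5 windows; both 50 epochs, Adam, ReLU output.
#'
#' @param kind `"mlp"` or `"lstm"`.
#' @param hidden Hidden-layer sizes.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param learning_rate Adam step size.
#' @param seq_len LSTM sequence length in windows.
#' @param grad_clip Global gradient-norm clip for the LSTM (stability guard).
#' @param seed Integer seed controlling init and shuffling.
#' @return A `model_config` list.
#' @export
model_config <- function(kind = c("mlp", "lstm"),
                         hidden = NULL, batch_size = NULL, epochs = 50,
                         learning_rate = NULL, seq_len = 5,
                         grad_clip = 1.0, seed = 1L) {
  kind <- match.arg(kind)
  defaults <- list(
    mlp = list(hidden = c(50, 30), batch_size = 125, learning_rate = 0.001),
    lstm = list(hidden = c(100, 200), batch_size = 256, learning_rate = 0.0001)
  )[[kind]]
  structure(
    list(kind = kind,
         hidden = hidden %||% defaults$hidden,
         batch_size = batch_size %||% defaults$batch_size,
         epochs = epochs,
         learning_rate = learning_rate %||% defaults$learning_rate,
         seq_len = seq_len, grad_clip = grad_clip, seed = as.integer(seed)),
    class = "model_config"
  )
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- dataset assembly ------------------------------------------------------

#' Assemble supervised pairs from features and a consensus target
#'
#' Joins each analysis window to the target sample nearest its end time
#' (within half a 5 s step; misalignment beyond one step is an error listing
#' the offending timestamps). For the MLP each window is one 8-vector; for
#' the LSTM, sliding sequences of `seq_len` consecutive windows (stride 1)
#' predict the target at the last window. Targets are scaled to \[0, 1\]
#' (score / 100).
#'
#' @param features A normalized `noci_features` tibble.
#' @param target Tibble with `time_s`, `score` (e.g. from [consensus()]).
#' @param kind `"mlp"` or `"lstm"`.
#' @param seq_len LSTM sequence length (default 5).
#' @return A `noci_dataset` list with elements `x` (matrix or 3-d array),
#'   `y`, `window_end_s`, `channels`, `kind`.
#' @export
make_dataset <- function(features, target, kind = c("mlp", "lstm"), seq_len = 5) {
  kind <- match.arg(kind)
  chans <- feature_channels()
  stopifnot(all(chans %in% names(features)),
            all(c("time_s", "score") %in% names(target)))
  # windows outside the target's covered span are trimmed (raters may start
  # late / stop early); remaining grids must agree within one 5 s step
  covered <- features$window_end_s >= min(target$time_s) - STEP_S / 2 &
    features$window_end_s <= max(target$time_s) + STEP_S / 2
  features <- features[covered, , drop = FALSE]
  if (nrow(features) == 0) abort("No feature windows fall inside the target span.")
  idx <- vapply(features$window_end_s, function(t) {
    which.min(abs(target$time_s - t))
  }, integer(1))
  gap <- abs(target$time_s[idx] - features$window_end_s)
  if (any(gap > STEP_S)) {
    bad <- features$window_end_s[gap > STEP_S]
    abort(sprintf("Feature and target grids misaligned beyond one 5 s step at: %s",
                  paste(utils::head(bad, 5), collapse = ", ")))
  }
  X <- as.matrix(features[, chans])
  y <- target$score[idx] / 100
  t_end <- features$window_end_s
  if (kind == "mlp") {
    ds <- list(kind = kind, x = X, y = y, window_end_s = t_end, channels = chans)
  } else {
    n <- nrow(X)
    if (n < seq_len) abort("Too few windows for one LSTM sequence.")
    starts <- seq_len(n - seq_len + 1L)
    # sequences must be 5 *consecutive* windows (5 s apart)
    ok <- vapply(starts, function(s) {
      all(abs(diff(t_end[s:(s + seq_len - 1L)]) - STEP_S) < 1e-6)
    }, logical(1))
    starts <- starts[ok]
    xs <- array(0, dim = c(length(starts), seq_len, length(chans)))
    for (j in seq_along(starts)) {
      xs[j, , ] <- X[starts[j]:(starts[j] + seq_len - 1L), ]
    }
    ds <- list(kind = kind, x = xs, y = y[starts + seq_len - 1L],
               window_end_s = t_end[starts + seq_len - 1L],
               channels = chans, seq_len = seq_len)
  }
  structure(ds, class = "noci_dataset")
}

# Concatenate datasets of the same kind (across patients).
bind_datasets <- function(ds_list) {
  kind <- ds_list[[1]]$kind
  stopifnot(all(vapply(ds_list, function(d) d$kind, character(1)) == kind))
  if (kind == "mlp") {
    x <- do.call(rbind, lapply(ds_list, `[[`, "x"))
  } else {
    ns <- vapply(ds_list, function(d) dim(d$x)[1], integer(1))
    x <- array(0, dim = c(sum(ns), dim(ds_list[[1]]$x)[2], dim(ds_list[[1]]$x)[3]))
    at <- 0L
    for (d in ds_list) {
      x[at + seq_len(dim(d$x)[1]), , ] <- d$x
      at <- at + dim(d$x)[1]
    }
  }
  structure(list(kind = kind, x = x,
                 y = unlist(lapply(ds_list, `[[`, "y")),
                 window_end_s = unlist(lapply(ds_list, `[[`, "window_end_s")),
                 channels = ds_list[[1]]$channels,
                 seq_len = ds_list[[1]]$seq_len),
            class = "noci_dataset")
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

clip_global_norm <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}

## ---- MLP -------------------------------------------------------------------

mlp_init <- function(d_in, hidden, seed) {
  local_seed(seed, {
    sizes <- c(d_in, hidden, 1L)
    params <- list()
    for (l in seq_len(length(sizes) - 1L)) {
      params[[paste0("W", l)]] <- matrix(
        rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
        sizes[l], sizes[l + 1L])
      params[[paste0("b", l)]] <- matrix(0, 1, sizes[l + 1L])
    }
    # Start the ReLU output at mid-scale with near-zero weights: the initial
    # prediction is the 0.5 bias, so the output unit is active everywhere and
    # cannot die en masse during the first, largest updates.
    L <- length(sizes) - 1L
    params[[paste0("W", L)]] <- params[[paste0("W", L)]] * 0.05
    params[[paste0("b", L)]][] <- 0.5
    params
  })
}

mlp_forward <- function(params, X) {
  L <- length(params) / 2L
  a <- X
  cache <- list(a0 = X)
  for (l in seq_len(L)) {
    z <- a %*% params[[paste0("W", l)]] +
      matrix(params[[paste0("b", l)]], nrow(a), ncol(params[[paste0("W", l)]]), byrow = TRUE)
    a <- relu(z)
    cache[[paste0("z", l)]] <- z
    cache[[paste0("a", l)]] <- a
  }
  list(yhat = a[, 1], cache = cache)
}

mlp_backward <- function(params, cache, yhat, y) {
  L <- length(params) / 2L
  B <- length(y)
  grads <- lapply(params, function(p) p * 0)
  delta <- matrix(2 * (yhat - y) / B, ncol = 1) * (cache[[paste0("z", L)]] > 0)
  for (l in L:1) {
    a_prev <- cache[[paste0("a", l - 1L)]]
    grads[[paste0("W", l)]] <- t(a_prev) %*% delta
    grads[[paste0("b", l)]] <- matrix(colSums(delta), 1)
    if (l > 1L) {
      delta <- (delta %*% t(params[[paste0("W", l)]])) * (cache[[paste0("z", l - 1L)]] > 0)
    }
  }
  grads
}

## ---- LSTM ------------------------------------------------------------------

lstm_init <- function(d_in, hidden, seed) {
  local_seed(seed, {
    params <- list()
    d <- d_in
    for (l in seq_along(hidden)) {
      H <- hidden[l]
      sdv <- 1 / sqrt(d + H)
      params[[paste0("Wx", l)]] <- matrix(rnorm(d * 4 * H, sd = sdv), d, 4 * H)
      params[[paste0("Wh", l)]] <- matrix(rnorm(H * 4 * H, sd = sdv), H, 4 * H)
      b <- matrix(0, 1, 4 * H)
      b[1, (H + 1):(2 * H)] <- 1  # forget-gate bias: remember by default
      params[[paste0("b", l)]] <- b
      d <- H
    }
    # near-zero head weights for the same reason as the MLP output layer
    params$Wy <- matrix(rnorm(d, sd = 0.01), d, 1)
    params$by <- matrix(0.5, 1, 1)
    params
  })
}

# Forward pass over a batch of sequences X (B x T x D). Returns prediction
# and the caches needed for backpropagation through time.
lstm_forward <- function(params, X, hidden) {
  B <- dim(X)[1]; Tn <- dim(X)[2]
  n_layers <- length(hidden)
  caches <- vector("list", n_layers)
  inputs <- lapply(seq_len(Tn), function(t) matrix(X[, t, ], nrow = B))
  for (l in seq_len(n_layers)) {
    H <- hidden[l]
    Wx <- params[[paste0("Wx", l)]]; Wh <- params[[paste0("Wh", l)]]
    b <- params[[paste0("b", l)]]
    h <- matrix(0, B, H); cc <- matrix(0, B, H)
    cache <- list(x = inputs, h = vector("list", Tn), c = vector("list", Tn),
                  gates = vector("list", Tn), c_prev = vector("list", Tn),
                  h_prev = vector("list", Tn))
    for (t in seq_len(Tn)) {
      z <- inputs[[t]] %*% Wx + h %*% Wh + matrix(b, B, 4 * H, byrow = TRUE)
      i <- sigmoid(z[, 1:H, drop = FALSE])
      f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
      g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
      o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
      cache$c_prev[[t]] <- cc
      cache$h_prev[[t]] <- h
      cc <- f * cc + i * g
      h <- o * tanh(cc)
      cache$gates[[t]] <- list(i = i, f = f, g = g, o = o)
      cache$c[[t]] <- cc
      cache$h[[t]] <- h
    }
    caches[[l]] <- cache
    inputs <- cache$h
  }
  hT <- inputs[[Tn]]
  zy <- hT %*% params$Wy + matrix(params$by, B, 1, byrow = TRUE)
  list(yhat = relu(zy)[, 1], zy = zy, hT = hT, caches = caches)
}

# Backpropagation through time for the stacked LSTM + ReLU head.
lstm_backward <- function(params, fwd, y, hidden) {
  B <- length(y); Tn <- length(fwd$caches[[1]]$x)
  n_layers <- length(hidden)
  grads <- lapply(params, function(p) p * 0)
  dzy <- matrix(2 * (fwd$yhat - y) / B, ncol = 1) * (fwd$zy > 0)
  grads$Wy <- t(fwd$hT) %*% dzy
  grads$by <- matrix(sum(dzy), 1, 1)
  # gradient wrt the top layer's hidden states: only the last step feeds the head
  dH_top <- vector("list", Tn)
  for (t in seq_len(Tn)) dH_top[[t]] <- matrix(0, B, hidden[n_layers])
  dH_top[[Tn]] <- dzy %*% t(params$Wy)
  dH <- dH_top
  for (l in n_layers:1) {
    H <- hidden[l]
    cache <- fwd$caches[[l]]
    Wx <- params[[paste0("Wx", l)]]; Wh <- params[[paste0("Wh", l)]]
    dWx <- Wx * 0; dWh <- Wh * 0; db <- matrix(0, 1, 4 * H)
    dX <- vector("list", Tn)
    dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
    for (t in Tn:1) {
      gt <- cache$gates[[t]]
      ct <- cache$c[[t]]
      tc <- tanh(ct)
      dh <- dH[[t]] + dh_next
      do_ <- dh * tc
      dct <- dh * gt$o * (1 - tc^2) + dc_next
      di <- dct * gt$g
      df <- dct * cache$c_prev[[t]]
      dg <- dct * gt$i
      dz <- cbind(di * gt$i * (1 - gt$i),
                  df * gt$f * (1 - gt$f),
                  dg * (1 - gt$g^2),
                  do_ * gt$o * (1 - gt$o))
      dWx <- dWx + t(cache$x[[t]]) %*% dz
      dWh <- dWh + t(cache$h_prev[[t]]) %*% dz
      db <- db + matrix(colSums(dz), 1)
      dX[[t]] <- dz %*% t(Wx)
      dh_next <- dz %*% t(Wh)
      dc_next <- dct * gt$f
    }
    grads[[paste0("Wx", l)]] <- dWx
    grads[[paste0("Wh", l)]] <- dWh
    grads[[paste0("b", l)]] <- db
    dH <- dX  # becomes the hidden-state gradient for the layer below
  }
  grads
}

## ---- training --------------------------------------------------------------

model_forward <- function(kind, params, x, hidden) {
  if (kind == "mlp") mlp_forward(params, x)$yhat
  else lstm_forward(params, x, hidden)$yhat
}

take_rows <- function(kind, x, idx) {
  if (kind == "mlp") x[idx, , drop = FALSE] else x[idx, , , drop = FALSE]
}

#' Train a nociception regressor
#'
#' Minibatch Adam on MSE for the configured number of epochs (no early
#' stopping); the LSTM additionally applies global gradient-norm clipping.
#' Per-epoch train/validation losses are recorded. Training is deterministic
#' under `config$seed`. Split training and validation by patient, never by
#' window, before calling.
#'
#' @param config A [model_config()].
#' @param train_ds,val_ds `noci_dataset`s from [make_dataset()] /
#'   `bind_datasets()`.
#' @return A `noci_model` with fitted weights, a `history` tibble and final
#'   train/validation R-squared.
#' @export
train_model <- function(config, train_ds, val_ds = NULL) {
  stopifnot(inherits(config, "model_config"), inherits(train_ds, "noci_dataset"),
            train_ds$kind == config$kind)
  kind <- config$kind
  d_in <- length(train_ds$channels)
  params <- if (kind == "mlp") mlp_init(d_in, config$hidden, config$seed)
            else lstm_init(d_in, config$hidden, config$seed)
  opt <- adam_init(params)
  n <- length(train_ds$y)
  history <- tibble(epoch = integer(0), train_loss = numeric(0), val_loss = numeric(0))
  local_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      order_idx <- sample.int(n)
      batch_starts <- seq(1L, n, by = config$batch_size)
      losses <- numeric(length(batch_starts))
      for (bi in seq_along(batch_starts)) {
        idx <- order_idx[batch_starts[bi]:min(batch_starts[bi] + config$batch_size - 1L, n)]
        xb <- take_rows(kind, train_ds$x, idx)
        yb <- train_ds$y[idx]
        if (kind == "mlp") {
          fwd <- mlp_forward(params, xb)
          grads <- mlp_backward(params, fwd$cache, fwd$yhat, yb)
          loss <- mean((fwd$yhat - yb)^2)
        } else {
          fwd <- lstm_forward(params, xb, config$hidden)
          grads <- lstm_backward(params, fwd, yb, config$hidden)
          grads <- clip_global_norm(grads, config$grad_clip)
          loss <- mean((fwd$yhat - yb)^2)
        }
        if (!is.finite(loss)) {
          abort(sprintf("NaN/Inf loss at epoch %d batch %d; aborting training.",
                        epoch, bi))
        }
        losses[bi] <- loss
        upd <- adam_step(params, grads, opt, config$learning_rate)
        params <- upd$params
        opt <- upd$state
      }
      val_loss <- if (is.null(val_ds)) NA_real_ else {
        vy <- model_forward(kind, params, val_ds$x, config$hidden)
        mean((vy - val_ds$y)^2)
      }
      history <- dplyr::bind_rows(history, tibble(
        epoch = epoch, train_loss = mean(losses), val_loss = val_loss))
    }
  })
  r2 <- function(ds) {
    if (is.null(ds)) return(NA_real_)
    p <- model_forward(kind, params, ds$x, config$hidden)
    1 - sum((p - ds$y)^2) / sum((ds$y - mean(ds$y))^2)
  }
  structure(
    list(kind = kind, config = config, params = params,
         channels = train_ds$channels, history = history,
         r2_train = r2(train_ds), r2_val = r2(val_ds)),
    class = "noci_model"
  )
}

#' @export
print.noci_model <- function(x, ...) {
  cat(sprintf("<noci_model> %s (%s), %d epochs, final train loss %.4g, R2 train %.3f\n",
              toupper(x$kind), paste(x$config$hidden, collapse = "/"),
              nrow(x$history), tail(x$history$train_loss, 1), x$r2_train))
  invisible(x)
}

#' Predict a nociception trace
#'
#' One prediction per window (MLP) or per complete sequence of 5 consecutive
#' windows (LSTM; the first prediction therefore lags the MLP's by 4 steps).
#' Features must be normalized with the same group reference used in
#' training; channels are matched by name. Output is rescaled to the 0--100
#' score and clipped.
#'
#' @param object A `noci_model`.
#' @param features A normalized `noci_features` tibble.
#' @param ... Unused.
#' @return Tibble with `window_end_s`, `prediction`.
#' @export
predict.noci_model <- function(object, features, ...) {
  missing_ch <- setdiff(object$channels, names(features))
  if (length(missing_ch)) {
    abort(sprintf("Feature channels missing vs training: %s",
                  paste(missing_ch, collapse = ", ")))
  }
  ds <- make_dataset(
    features,
    target = tibble(time_s = features$window_end_s, score = 0),
    kind = object$kind, seq_len = object$config$seq_len)
  p <- model_forward(object$kind, object$params, ds$x, object$config$hidden)
  tibble(window_end_s = ds$window_end_s,
         prediction = pmin(100, pmax(0, p * 100)))
}

#' Save / load a fitted model as JSON
#'
#' Weights, configuration, channel names and training history serialize to a
#' plain-text JSON checkpoint that reloads to an identical predictor.
#'
#' @param model A `noci_model`.
#' @param path File path (`.json`).
#' @return `save_model()` returns `path` invisibly; `load_model()` returns a
#'   `noci_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "noci_model"))
  payload <- list(
    kind = model$kind,
    config = unclass(model$config),
    channels = model$channels,
    params = model$params,
    history = model$history,
    r2_train = model$r2_train,
    r2_val = model$r2_val
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(p$params, function(m) {
    if (is.null(dim(m))) matrix(m, nrow = 1) else m
  })
  structure(
    list(kind = p$kind,
         config = structure(as.list(p$config), class = "model_config"),
         params = params, channels = p$channels,
         history = as_tibble(p$history),
         r2_train = p$r2_train, r2_val = p$r2_val),
    class = "noci_model"
  )
}

#' Tidy a fitted model's training history
#' @param x A `noci_model`.
#' @param ... Unused.
#' @return Tibble with one row per epoch and phase (`train`/`validation`).
#' @export
tidy.noci_model <- function(x, ...) {
  x$history |>
    tidyr::pivot_longer(c("train_loss", "val_loss"),
                        names_to = "phase", values_to = "loss") |>
    dplyr::mutate(phase = ifelse(.data$phase == "train_loss", "train", "validation")) |>
    dplyr::filter(is.finite(.data$loss))
}

#' One-row model summary
#' @param x A `noci_model`.
#' @param ... Unused.
#' @return Tibble with kind, final losses and R-squared values.
#' @export
glance.noci_model <- function(x, ...) {
  tibble(kind = x$kind,
         epochs = nrow(x$history),
         train_loss = tail(x$history$train_loss, 1),
         val_loss = tail(x$history$val_loss, 1),
         r2_train = x$r2_train,
         r2_val = x$r2_val)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
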