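# Sequence forecasting of feeding intensity: 50-step context windows of
# [s_i, t_i, S, D, V, Phi] predict either the next 5-s window sum (scalar
# mode) or the next 50 per-sample sums (trajectory mode, consumed by the
# controller).

#' Forecaster architecture configuration
#'
#' Defaults mirror the reference architecture: two stacked recurrent layers
#' of 128 tanh units, dropout 0.2, a 64-unit ReLU dense layer and a linear
#' output head; the transformer variant uses two single-head self-attention
#' encoder layers (model width 128, feed-forward width 256) with sinusoidal
#' positional encoding over the 50-step context.
#'
#' @param arch `"lstm"`, `"gru"` or `"transformer"`.
#' @param units Recurrent units per layer (default 128).
#' @param dense_units Width of the ReLU dense layer (default 64).
#' @param dropout Dropout rate after feature extraction (default 0.2).
#' @param output_dim 1 (scalar mode) or 50 (trajectory mode); normally set
#'   from the supervised set by [train_forecaster()].
#' @param d_model,ff_dim Transformer model and feed-forward widths.
#' @return Object of class `"model_config"`.
#' @export
model_config <- function(arch = c("lstm", "gru", "transformer"), units = 128,
                         dense_units = 64, dropout = 0.2, output_dim = NULL,
                         d_model = 128, ff_dim = 256) {
  arch <- match.arg(arch)
  stopifnot(units >= 1, dense_units >= 1, dropout >= 0, dropout < 1)
  if (!is.null(output_dim) && !output_dim %in% c(1L, 50L)) {
    stop("`output_dim` must be 1 (scalar) or 50 (trajectory)", call. = FALSE)
  }
  structure(list(arch = arch, units = units, dense_units = dense_units,
                 dropout = dropout, output_dim = output_dim,
                 d_model = d_model, ff_dim = ff_dim),
            class = "model_config")
}

#' Training configuration
#'
#' @param lr Adam learning rate (default 0.001).
#' @param batch_size Minibatch size (default 32).
#' @param max_epochs Epoch cap (default 200).
#' @param patience Early-stopping patience on validation loss (default 20);
#'   the best-validation weights are restored.
#' @param seed Integer seed covering initialization, shuffling and dropout.
#' @param verbose Print one line per epoch.
#' @return Object of class `"train_config"`.
#' @export
train_config <- function(lr = 0.001, batch_size = 32, max_epochs = 200,
                         patience = 20, seed = 1L, verbose = FALSE) {
  stopifnot(lr > 0, batch_size >= 1, max_epochs >= 1, patience >= 1)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

.trace_features <- function(trace, filter_cfg) {
  cfg <- trace$meta$config
  if (is.null(cfg)) {
    stop("trace lacks trial metadata needed for static features",
         call. = FALSE)
  }
  s <- triaxial_sum(trace, filter_cfg)
  cbind(s = s, t = trace$time, S = cfg$size_g, D = cfg$density,
        V = cfg$feed_rate, Phi = cfg$pellet_mm)
}

#' Build supervised forecasting windows from trials
#'
#' Slides a `context_len`-step window over each trial's per-step feature
#' vectors `[s_i, t_i, S, D, V, Phi]` (statics broadcast per step). The
#' target immediately follows the context with no gap: in scalar mode the
#' sum of the next 50 per-sample sums (the next window sum, um); in
#' trajectory mode the next 50 per-sample sums themselves. Samples are
#' split at random into training and validation sets and feature
#' normalization statistics are fitted on the training split only; targets
#' are kept in um.
#'
#' @param trials A `"trial_dataset"`, a list of [triaxial_trace()]s, or a
#'   single trace.
#' @param context_len Context length in samples (default 50).
#' @param stride Window stride in samples (default 1).
#' @param mode `"scalar"` or `"trajectory"`.
#' @param val_fraction Held-out fraction (default 0.2).
#' @param seed Seed for the random split (and subsampling).
#' @param filter_cfg Amplitude gate applied to each trial before feature
#'   extraction; defaults to the synthetic-scale gate.
#' @param max_samples Optional cap: a seeded random subsample of windows is
#'   kept, preserving the split fractions. Used to scale training runs down.
#' @return Object of class `"supervised_set"`: feature array `x`
#'   (N x context_len x 6, raw scale), targets `y`, logical `is_train`,
#'   fitted `feature_stats` and `target_stats` (training split only).
#' @export
build_supervised <- function(trials, context_len = 50L, stride = 1L,
                             mode = c("scalar", "trajectory"),
                             val_fraction = 0.2, seed = 1L,
                             filter_cfg = synthetic_filter_threshold(),
                             max_samples = NULL) {
  mode <- match.arg(mode)
  if (inherits(trials, "trial_dataset")) trials <- trials$traces
  if (inherits(trials, "triaxial_trace")) trials <- list(trials)
  stopifnot(val_fraction > 0, val_fraction < 1)
  context_len <- as.integer(context_len)
  horizon <- 50L
  xs <- list(); ys <- list()
  for (tr in trials) {
    feats <- .trace_features(tr, filter_cfg)
    n <- nrow(feats)
    need <- context_len + horizon
    if (n < need) {
      warning(sprintf("trial of %d samples too short for %d-step windows; skipped",
                      n, need))
      next
    }
    starts <- seq(1L, n - need + 1L, by = stride)
    for (st in starts) {
      xs[[length(xs) + 1L]] <- feats[st:(st + context_len - 1L), , drop = FALSE]
      tgt <- feats[(st + context_len):(st + need - 1L), "s"]
      ys[[length(ys) + 1L]] <- if (mode == "scalar") sum(tgt) else tgt
    }
  }
  if (!length(xs)) stop("no trial long enough to build windows", call. = FALSE)
  n_samp <- length(xs)
  x <- array(0, c(n_samp, context_len, 6L),
             dimnames = list(NULL, NULL, colnames(xs[[1]])))
  for (i in seq_len(n_samp)) x[i, , ] <- xs[[i]]
  y <- if (mode == "scalar") vapply(ys, identity, numeric(1)) else
    do.call(rbind, ys)
  .with_seed(seed, {
    if (!is.null(max_samples) && max_samples < n_samp) {
      keep <- sort(sample.int(n_samp, max_samples))
      x <- x[keep, , , drop = FALSE]
      y <- if (is.matrix(y)) y[keep, , drop = FALSE] else y[keep]
      n_samp <- max_samples
    }
    n_val <- max(1L, round(val_fraction * n_samp))
    val_idx <- sample.int(n_samp, n_val)
  })
  is_train <- !seq_len(n_samp) %in% val_idx
  flat <- matrix(x[is_train, , , drop = FALSE],
                 ncol = 6L, dimnames = list(NULL, dimnames(x)[[3]]))
  feature_stats <- zscore_fit(flat, constant_ok = TRUE)
  ytr <- if (is.matrix(y)) as.numeric(y[is_train, ]) else y[is_train]
  target_stats <- zscore_fit(matrix(ytr, ncol = 1L), constant_ok = TRUE)
  structure(list(x = x, y = y, mode = mode, context_len = context_len,
                 horizon = horizon, is_train = is_train,
                 feature_stats = feature_stats, target_stats = target_stats,
                 seed = seed),
            class = "supervised_set")
}

#' @export
print.supervised_set <- function(x, ...) {
  cat(sprintf("Supervised set (%s mode): %d windows (%d train / %d val), context %d steps\n",
              x$mode, dim(x$x)[1], sum(x$is_train), sum(!x$is_train),
              x$context_len))
  invisible(x)
}

.normalize_x <- function(x, stats) {
  dims <- dim(x)
  array(zscore_apply(matrix(x, ncol = dims[3]), stats), dims)
}

.normalize_y <- function(y, stats) {
  (y - stats$mean) / stats$sd
}

.denormalize_y <- function(y, stats) {
  y * stats$sd + stats$mean
}

.batched_predict_norm <- function(net, xn, batch = 256L) {
  n <- dim(xn)[1]
  out <- NULL
  for (st in seq(1L, n, by = batch)) {
    en <- min(n, st + batch - 1L)
    yb <- .nn_forward(net, xn[st:en, , , drop = FALSE], training = FALSE)$y
    out <- rbind(out, yb)
  }
  out
}

#' Train a feeding-intensity forecaster
#'
#' Trains the configured architecture with Adam on mean-squared error,
#' minibatched, with early stopping on validation loss (best weights
#' restored). Features and targets are normalized internally with the
#' supervised set's training-split statistics; all reported predictions and
#' metrics are on the original um scale. Fully deterministic for a fixed
#' seed.
#'
#' @param data A [build_supervised()] set.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @return Object of class `"feed_forecaster"`.
#' @export
train_forecaster <- function(data, model_cfg = model_config(),
                             train_cfg = train_config()) {
  stopifnot(inherits(data, "supervised_set"),
            inherits(model_cfg, "model_config"),
            inherits(train_cfg, "train_config"))
  out_dim <- if (data$mode == "scalar") 1L else data$horizon
  if (!is.null(model_cfg$output_dim) && model_cfg$output_dim != out_dim) {
    stop("model output_dim does not match the supervised set mode",
         call. = FALSE)
  }
  model_cfg$output_dim <- out_dim
  xn <- .normalize_x(data$x, data$feature_stats)
  yn <- .normalize_y(if (is.matrix(data$y)) data$y else
    matrix(data$y, ncol = 1L), data$target_stats)
  tr_ix <- which(data$is_train)
  va_ix <- which(!data$is_train)
  if (length(tr_ix) < 2L * train_cfg$batch_size) {
    warning("fewer than two batches of training data")
  }
  x_va <- xn[va_ix, , , drop = FALSE]
  y_va <- yn[va_ix, , drop = FALSE]
  .with_seed(train_cfg$seed, {
    net <- .nn_init(model_cfg$arch, input_dim = dim(xn)[3],
                    output_dim = out_dim, cfg = model_cfg)
    opt <- .adam_init(net$params)
    best <- list(loss = Inf, params = net$params, epoch = 0L)
    history <- data.frame(epoch = integer(), train_mse = numeric(),
                          val_mse = numeric())
    wait <- 0L
    for (epoch in seq_len(train_cfg$max_epochs)) {
      perm <- sample(tr_ix)
      tot <- 0; nb <- 0L
      for (st in seq(1L, length(perm), by = train_cfg$batch_size)) {
        en <- min(length(perm), st + train_cfg$batch_size - 1L)
        ix <- perm[st:en]
        xb <- xn[ix, , , drop = FALSE]
        yb <- yn[ix, , drop = FALSE]
        fwd <- .nn_forward(net, xb, training = TRUE)
        err <- fwd$y - yb
        loss <- mean(err^2)
        if (!is.finite(loss)) {
          stop(sprintf(
            "divergent loss (%.3g) at epoch %d, batch %d; lower the learning rate",
            loss, epoch, nb + 1L), call. = FALSE)
        }
        grads <- .nn_backward(net, xb, fwd, 2 * err / length(err))
        stepped <- .adam_step(net$params, grads, opt, lr = train_cfg$lr)
        net$params <- stepped$params
        opt <- stepped$state
        tot <- tot + loss * length(ix); nb <- nb + 1L
      }
      val_pred <- .batched_predict_norm(net, x_va)
      val_mse <- mean((val_pred - y_va)^2)
      history <- rbind(history, data.frame(
        epoch = epoch, train_mse = tot / length(perm), val_mse = val_mse))
      if (train_cfg$verbose) {
        message(sprintf("epoch %3d  train MSE %.5f  val MSE %.5f", epoch,
                        tot / length(perm), val_mse))
      }
      if (val_mse < best$loss - 1e-12) {
        best <- list(loss = val_mse, params = net$params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= train_cfg$patience) break
      }
    }
    net$params <- best$params
  })
  structure(list(arch = model_cfg$arch, net = net, model_cfg = model_cfg,
                 train_cfg = train_cfg, mode = data$mode,
                 context_len = data$context_len,
                 feature_stats = data$feature_stats,
                 target_stats = data$target_stats,
                 history = history, best_epoch = best$epoch),
            class = "feed_forecaster")
}

#' @export
print.feed_forecaster <- function(x, ...) {
  cat(sprintf("Feeding-intensity forecaster (%s, %s mode)\n", toupper(x$arch),
              x$mode))
  cat(sprintf("  trained %d epochs (best at %d), final val MSE %.5f (normalized)\n",
              nrow(x$history), x$best_epoch, min(x$history$val_mse)))
  invisible(x)
}

#' @export
summary.feed_forecaster <- function(object, ...) {
  print(object)
  cat(sprintf("  context %d steps, output dim %d, %d parameters\n",
              object$context_len, object$model_cfg$output_dim,
              length(.flatten_params(object$net$params))))
  invisible(object)
}

#' Predict feeding intensity from context windows
#'
#' @param object A `"feed_forecaster"`.
#' @param newdata A `"supervised_set"`, or a raw feature array
#'   (N x context_len x 6) or single context matrix (context_len x 6) on
#'   the original um scale.
#' @param ... Unused.
#' @return Scalar mode: numeric vector of predicted next-window sums (um).
#'   Trajectory mode: N x 50 matrix of predicted per-sample sums (um).
#' @export
predict.feed_forecaster <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "supervised_set")) newdata$x else newdata
  if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x)))
  if (length(dim(x)) != 3L || dim(x)[2] != object$context_len ||
      dim(x)[3] != length(object$feature_stats$mean)) {
    stop(sprintf("context shape mismatch: expected N x %d x %d",
                 object$context_len, length(object$feature_stats$mean)),
         call. = FALSE)
  }
  xn <- .normalize_x(x, object$feature_stats)
  yn <- .batched_predict_norm(object$net, xn)
  y <- .denormalize_y(yn, object$target_stats)
  if (object$mode == "scalar") as.numeric(y) else y
}

#' Forecast accuracy metrics
#'
#' RMSE, MAE and the coefficient of determination, computed on de-normalized
#' (um-scale) targets.
#'
#' @param model A `"feed_forecaster"`.
#' @param data A `"supervised_set"` built with the same mode.
#' @param subset `"val"` (default), `"train"` or `"all"`.
#' @return Object of class `"forecast_metrics"` with `rmse`, `mae`,
#'   `r_squared` and `n`.
#' @export
evaluate_forecaster <- function(model, data, subset = c("val", "train", "all")) {
  stopifnot(inherits(model, "feed_forecaster"),
            inherits(data, "supervised_set"))
  subset <- match.arg(subset)
  keep <- switch(subset, val = !data$is_train, train = data$is_train,
                 all = rep(TRUE, length(data$is_train)))
  if (!any(keep)) stop("empty evaluation subset", call. = FALSE)
  x <- data$x[keep, , , drop = FALSE]
  y <- if (is.matrix(data$y)) data$y[keep, , drop = FALSE] else data$y[keep]
  pred <- predict(model, x)
  out <- .forecast_metrics(as.numeric(pred), as.numeric(y))
  out$subset <- subset
  out
}

# metric formulas shared by evaluate_forecaster and the comparison table
.forecast_metrics <- function(pred, y) {
  err <- pred - y
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("zero target variance; R^2 undefined", call. = FALSE)
  structure(list(rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
                 r_squared = 1 - sum(err^2) / ss_tot, n = length(y),
                 subset = "all"),
            class = "forecast_metrics")
}

#' @export
print.forecast_metrics <- function(x, ...) {
  cat(sprintf("Forecast metrics (%s, n = %d): RMSE = %.2f um, MAE = %.2f um, R^2 = %.3f\n",
              x$subset, x$n, x$rmse, x$mae, x$r_squared))
  invisible(x)
}

#' Train and evaluate all three architectures on identical splits
#'
#' One row per architecture per seed; the split, normalization and training
#' configuration are shared so the comparison isolates the architecture.
#' The ranking on synthetic data is recorded, not asserted.
#'
#' @param data A [build_supervised()] set.
#' @param seeds Integer vector of training seeds.
#' @param archs Architectures to include.
#' @param model_args Named list of [model_config()] overrides applied to all
#'   architectures (e.g. smaller `units` for quick runs).
#' @param train_cfg Shared [train_config()]; its seed is replaced per run.
#' @return Data frame `arch, seed, rmse_um, mae_um, r2`.
#' @export
compare_architectures <- function(data, seeds = 1L,
                                  archs = c("lstm", "gru", "transformer"),
                                  model_args = list(),
                                  train_cfg = train_config()) {
  rows <- list()
  for (arch in archs) {
    mc <- do.call(model_config, c(list(arch = arch), model_args))
    for (sd_ in seeds) {
      tc <- train_cfg
      tc$seed <- as.integer(sd_)
      fit <- train_forecaster(data, mc, tc)
      m <- evaluate_forecaster(fit, data, subset = "val")
      rows[[length(rows) + 1L]] <- data.frame(
        arch = arch, seed = sd_, rmse_um = m$rmse, mae_um = m$mae,
        r2 = m$r_squared)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
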