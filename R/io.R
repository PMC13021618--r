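# Flat-file I/O: trace CSV (t,x_um,y_um,z_um), window CSV, dataset
# manifests and JSON summaries. No binary formats; every artifact records
# the seed it was produced with.

#' Write and read a triaxial trace CSV
#'
#' Schema: header `t,x_um,y_um,z_um`, one row per sample. A write/read
#' round trip reproduces values to formatting precision (15 significant
#' digits).
#'
#' @param trace A [triaxial_trace()].
#' @param path File path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   [triaxial_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "triaxial_trace"))
  df <- data.frame(t = trace$time, x_um = trace$x, y_um = trace$y,
                   z_um = trace$z)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param fs Sampling rate the file is expected to carry (default 10 Hz).
#' @export
read_trace <- function(path, fs = 10) {
  if (!file.exists(path)) stop("no such trace file: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path), error = function(e) {
    stop("cannot parse trace CSV ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  if (nrow(df) == 0L) stop("empty-trace error: ", path, call. = FALSE)
  need <- c("t", "x_um", "y_um", "z_um")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("trace CSV missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in need) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad)) {
      stop(sprintf("non-finite value in column %s at data line %d of %s",
                   col, bad[1], path), call. = FALSE)
    }
  }
  dt <- diff(df$t)
  bad <- which(dt <= 0)
  if (length(bad)) {
    stop(sprintf("non-monotone time at data line %d of %s", bad[1] + 1L, path),
         call. = FALSE)
  }
  triaxial_trace(df$x_um, df$y_um, df$z_um, fs = fs, time = df$t)
}

#' Write a window series CSV
#'
#' Schema: `k,t_start,d_sum_um,h_max_um`.
#'
#' @param ws A `"window_series"`.
#' @param path File path.
#' @export
write_windows <- function(ws, path) {
  stopifnot(inherits(ws, "window_series"))
  df <- data.frame(k = seq_along(ws$d_sum) - 1L,
                   t_start = ws$window_start_times,
                   d_sum_um = ws$d_sum, h_max_um = ws$h_max)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a generated dataset to disk
#'
#' Traces go to `<dir>/traces/<trial_id>.csv`; the manifest
#' (`trial_id,size_g,density,feed_rate,pellet_mm,duration_s,seed,trace_path`)
#' to `<dir>/manifest.csv`.
#'
#' @param dataset A `"trial_dataset"`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "trial_dataset"))
  tr_dir <- file.path(dir, "traces")
  dir.create(tr_dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  man$trace_path <- file.path("traces", paste0(man$trial_id, ".csv"))
  for (i in seq_len(nrow(man))) {
    write_trace(dataset$traces[[man$trial_id[i]]], file.path(dir, man$trace_path[i]))
  }
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man[c("trial_id", "size_g", "density", "feed_rate",
                         "pellet_mm", "duration_s", "seed", "trace_path")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory containing `manifest.csv`.
#' @return A `"trial_dataset"` (traces carry their manifest conditions as
#'   metadata).
#' @export
read_dataset <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  traces <- lapply(seq_len(nrow(man)), function(i) {
    tr <- read_trace(file.path(dir, man$trace_path[i]))
    tr$meta <- list(config = trial_config(
      size_g = man$size_g[i], density = man$density[i],
      feed_rate = man$feed_rate[i], pellet = man$pellet_mm[i],
      duration_s = man$duration_s[i], seed = man$seed[i]))
    tr
  })
  names(traces) <- man$trial_id
  structure(list(manifest = man, traces = traces, master_seed = NA_integer_),
            class = "trial_dataset")
}

#' Write a characterization report
#'
#' Per-level CSV (`level,mean_peak_um,sd_peak_um,n`) plus a JSON summary
#' with the fitted line and the top-vs-bottom percent increase.
#'
#' @param chr An `"experiment_characterization"`.
#' @param dir Output directory.
#' @return Invisibly, the JSON path.
#' @export
write_characterization <- function(chr, dir) {
  stopifnot(inherits(chr, "experiment_characterization"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(chr$summary[c("level", "mean_peak_um", "sd_peak_um", "n")],
                   file.path(dir, paste0(chr$experiment, "_levels.csv")),
                   row.names = FALSE, quote = FALSE)
  summ <- list(experiment = chr$experiment, seed = chr$seed,
               percent_increase_top_vs_bottom =
                 chr$percent_increase_top_vs_bottom)
  if (!is.null(chr$fit)) {
    summ <- c(summ, list(slope = chr$fit$slope, intercept = chr$fit$intercept,
                         r_squared = chr$fit$r_squared))
  }
  path <- file.path(dir, paste0(chr$experiment, "_summary.json"))
  jsonlite::write_json(summ, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Save and load a trained forecaster
#'
#' The artifact is a directory: flat weight vector as CSV plus a JSON
#' sidecar with architecture, configs, normalization statistics and
#' training history.
#'
#' @param model A `"feed_forecaster"`.
#' @param dir Artifact directory.
#' @return `save_forecaster` returns `dir` invisibly; `load_forecaster`
#'   returns the model.
#' @export
save_forecaster <- function(model, dir) {
  stopifnot(inherits(model, "feed_forecaster"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- .flatten_params(model$net$params)
  utils::write.csv(data.frame(w = w), file.path(dir, "weights.csv"),
                   row.names = FALSE)
  side <- list(arch = model$arch, mode = model$mode,
               context_len = model$context_len,
               model_cfg = unclass(model$model_cfg),
               train_cfg = unclass(model$train_cfg),
               feature_stats = list(mean = model$feature_stats$mean,
                                    sd = model$feature_stats$sd),
               target_stats = list(mean = model$target_stats$mean,
                                   sd = model$target_stats$sd),
               best_epoch = model$best_epoch,
               history = model$history)
  jsonlite::write_json(side, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_forecaster
#' @export
load_forecaster <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  mc <- do.call(model_config, side$model_cfg[c("arch", "units", "dense_units",
                                               "dropout", "d_model",
                                               "ff_dim")])
  mc$output_dim <- side$model_cfg$output_dim
  tc <- do.call(train_config, side$train_cfg[c("lr", "batch_size",
                                               "max_epochs", "patience",
                                               "seed", "verbose")])
  net <- .with_seed(1L, .nn_init(side$arch, input_dim =
                                   length(side$feature_stats$mean),
                                 output_dim = mc$output_dim, cfg = mc))
  w <- utils::read.csv(file.path(dir, "weights.csv"))$w
  net$params <- .unflatten_params(net$params, w)
  fstats <- structure(list(mean = unlist(side$feature_stats$mean),
                           sd = unlist(side$feature_stats$sd)),
                      class = "zscore_stats")
  tstats <- structure(list(mean = unlist(side$target_stats$mean),
                           sd = unlist(side$target_stats$sd)),
                      class = "zscore_stats")
  structure(list(arch = side$arch, net = net, model_cfg = mc, train_cfg = tc,
                 mode = side$mode, context_len = side$context_len,
                 feature_stats = fstats, target_stats = tstats,
                 history = as.data.frame(side$history),
                 best_epoch = side$best_epoch),
            class = "feed_forecaster")
}

#' Write a session summary JSON
#'
#' @param session A `"feeding_session"`.
#' @param path JSON path.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "feeding_session"))
  jsonlite::write_json(list(total_fed_g = session$total_fed,
                            residual_g = session$residual,
                            rfr_pct = session$rfr,
                            stop_time_s = session$stop_time,
                            seed = session$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
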