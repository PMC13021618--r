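# Parametric characterization of feeding responses: peak extraction, linear
# response fits, percent-increase contrasts, peak timing and fluctuation
# frequency.

#' Peak windowed displacement
#'
#' Maximum window sum of a [window_sums()] series and the index of the
#' window attaining it; ties resolve to the earliest window.
#'
#' @param ws A `"window_series"`.
#' @return List with `peak` (um) and `index` (1-based window index).
#' @export
peak_displacement <- function(ws) {
  stopifnot(inherits(ws, "window_series"))
  if (length(ws$d_sum) == 0L) stop("empty window series", call. = FALSE)
  idx <- which.max(ws$d_sum)
  list(peak = ws$d_sum[idx], index = idx)
}

#' Time of the peak window
#'
#' Midpoint (start time plus half the window length) of the window with the
#' largest summed displacement.
#'
#' @inheritParams peak_displacement
#' @return Time in seconds.
#' @export
peak_time <- function(ws) {
  stopifnot(inherits(ws, "window_series"))
  if (length(ws$d_sum) == 0L) stop("empty window series", call. = FALSE)
  idx <- which.max(ws$d_sum)
  ws$window_start_times[idx] + ws$window_len / (2 * ws$fs)
}

#' Equal-weight ordinary least squares line
#'
#' Closed-form OLS fit with intercept; `r_squared = 1 - SS_res / SS_tot`.
#'
#' @param x Numeric predictor (factor levels); at least 2 distinct values.
#' @param y Numeric response (um).
#' @return Object of class `"linear_fit"` with `slope`, `intercept`,
#'   `r_squared` and `n`.
#' @export
#' @examples
#' fit_line(c(50, 150, 300), calibrate_group_means(c(50, 150, 300),
#'                                                 1.7316, 236.41, 2.097))
fit_line <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y) || n < 2L) stop("need n >= 2 paired points", call. = FALSE)
  if (sd(x) == 0) stop("all x values identical; slope undefined", call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(slope = slope, intercept = intercept, r_squared = r2, n = n),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit (n = %d): y = %.4f x + %.2f, R^2 = %.4f\n",
              x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Percent increase of a value over a reference
#'
#' @param reference Reference value (> 0).
#' @param value Comparison value.
#' @return `100 * (value - reference) / reference`.
#' @export
#' @examples
#' percent_increase(100, 200)
percent_increase <- function(reference, value) {
  if (any(reference <= 0)) {
    stop("`reference` must be > 0", call. = FALSE)
  }
  100 * (value - reference) / reference
}

#' Mean-crossing fluctuation frequency
#'
#' Operationalizes "fluctuation frequency" as the mean-crossing rate: the
#' series mean is subtracted, sign changes are counted (zeros keep the
#' previous sign), and the count is divided by twice the series duration.
#' A constant series has frequency 0.
#'
#' @param s Numeric series (>= 2 samples).
#' @param fs Sampling rate in Hz.
#' @return Frequency in Hz.
#' @export
#' @examples
#' t <- seq(0, 10 - 0.1, by = 0.1)
#' zero_crossing_frequency(sin(2 * pi * 2 * t), fs = 10)
zero_crossing_frequency <- function(s, fs = 10) {
  if (length(s) < 2L) stop("need at least 2 samples", call. = FALSE)
  x <- s - mean(s)
  sgn <- sign(x)
  # zeros attach to the previous sign
  for (i in seq_along(sgn)) {
    if (sgn[i] == 0) sgn[i] <- if (i > 1L) sgn[i - 1L] else 1
  }
  crossings <- sum(diff(sgn) != 0)
  crossings / (2 * (length(s) / fs))
}

#' Fluctuation frequency of the feeding burst
#'
#' The mean-crossing rate measured on the high-activity segment of a trial:
#' the peak window of the per-sample sum plus one window on each side.
#' Within that segment the intensity envelope is nearly flat, so the
#' mean-crossing rate recovers the oscillation frequency of the burst;
#' applied to a whole trial the envelope's rise and decay would dominate
#' the global mean and mask the oscillation.
#'
#' @param s Per-sample triaxial sum series (um).
#' @param fs Sampling rate (Hz).
#' @param window_len Analysis window length in samples (default 50).
#' @return Frequency in Hz.
#' @export
fluctuation_frequency <- function(s, fs = 10, window_len = 50) {
  ws <- window_sums(s, window_len = window_len, fs = fs)
  k <- peak_displacement(ws)$index
  lo <- max(1L, (k - 2L) * window_len + 1L)
  hi <- min(length(s), (k + 1L) * window_len)
  zero_crossing_frequency(s[lo:hi], fs = fs)
}

.EXPERIMENT_LEVELS <- list(
  size = list(factor = "size_g", levels = c(50, 150, 300)),
  density = list(factor = "density", levels = c(20, 40, 60)),
  rate = list(factor = "feed_rate", levels = c(1, 2, 3)),
  pellet = list(factor = "pellet_mm", levels = c(3, 5, 7))
)

#' Run and characterize one single-factor experiment
#'
#' Generates `replicates` seeded trials per factor level of the chosen
#' experiment, extracts per-trial peak displacement, peak time and
#' fluctuation frequency, and summarizes: per-level mean/sd tables, an OLS
#' fit of peak displacement against the factor level (size and density
#' experiments), and the top-vs-bottom percent increase of group means.
#'
#' @param experiment One of `"size"`, `"density"`, `"rate"`, `"pellet"`.
#' @param replicates Trials per level (default 6: two tanks, three trials).
#' @param seed Master seed for per-trial seeds.
#' @param params A [generator_params()].
#' @param profiles See [default_profiles()].
#' @return Object of class `"experiment_characterization"`.
#' @export
characterize_experiment <- function(experiment = c("size", "density", "rate",
                                                   "pellet"),
                                    replicates = 6, seed = 1L,
                                    params = generator_params(),
                                    profiles = default_profiles()) {
  experiment <- match.arg(experiment)
  exp_def <- .EXPERIMENT_LEVELS[[experiment]]
  base <- default_design(replicates = 1)
  base <- base[base$experiment == experiment, ]
  seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                       length(exp_def$levels) * replicates))
  rows <- list()
  i <- 0L
  for (li in seq_along(exp_def$levels)) {
    row <- base[li, ]
    loadings <- NULL
    for (r in seq_len(replicates)) {
      i <- i + 1L
      cfg <- trial_config(size_g = row$size_g, density = row$density,
                          feed_rate = row$feed_rate, pellet = row$pellet_mm,
                          duration_s = row$duration_s, seed = seeds[i])
      tr <- generate_trial(cfg, params, profiles, loadings = loadings)
      if (is.null(loadings)) loadings <- tr$meta$loadings
      s <- triaxial_sum(tr, synthetic_filter_threshold(params))
      ws <- window_sums(s, fs = tr$fs)
      rows[[i]] <- data.frame(
        level = exp_def$levels[li],
        peak_um = peak_displacement(ws)$peak,
        peak_time_s = peak_time(ws),
        freq_hz = fluctuation_frequency(s, fs = tr$fs))
    }
  }
  trials <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(trials, trials$level), function(d) {
    data.frame(level = d$level[1], mean_peak_um = mean(d$peak_um),
               sd_peak_um = sd(d$peak_um), mean_peak_time_s = mean(d$peak_time_s),
               mean_freq_hz = mean(d$freq_hz), n = nrow(d))
  }))
  rownames(agg) <- NULL
  fit <- if (experiment %in% c("size", "density")) {
    fit_line(trials$level, trials$peak_um)
  }
  inc <- percent_increase(agg$mean_peak_um[1],
                          agg$mean_peak_um[nrow(agg)])
  structure(list(experiment = experiment, factor = exp_def$factor,
                 trials = trials, summary = agg, fit = fit,
                 percent_increase_top_vs_bottom = inc, seed = seed),
            class = "experiment_characterization")
}

#' @export
print.experiment_characterization <- function(x, ...) {
  cat(sprintf("Characterization of the %s experiment (%d trials/level):\n",
              x$experiment, x$summary$n[1]))
  print(x$summary, row.names = FALSE)
  if (!is.null(x$fit)) print(x$fit)
  cat(sprintf("  top vs bottom level: +%.1f%% mean peak displacement\n",
              x$percent_increase_top_vs_bottom))
  invisible(x)
}
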