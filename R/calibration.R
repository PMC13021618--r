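# Calibration of the synthetic generator against published response curves:
# group means are solved so that an equal-weight OLS refit reproduces the
# published regression line exactly while the top/bottom group ratio matches
# the published percent increase. The two constraints are deliberately
# honoured jointly - the means do not lie exactly on the line, consistent
# with a reported R^2 < 1.

#' Solve three group means from a regression line and a group ratio
#'
#' Given three factor levels, a published OLS slope and intercept for the
#' response at those levels, and the published ratio between the top and
#' bottom group means, solves the unique 3x3 linear system such that (a)
#' equal-weight OLS through `(level_i, mu_i)` returns exactly the given slope
#' and intercept and (b) `mu_3 = ratio * mu_1`.
#'
#' @param levels Numeric vector of 3 distinct, increasing factor levels.
#' @param slope,intercept Published regression coefficients (um per unit, um).
#' @param ratio Top-level / bottom-level mean ratio (> 0), e.g. 2.097 for a
#'   reported 109.7 percent increase.
#' @return Named numeric vector of 3 group means (um).
#' @export
#' @examples
#' calibrate_group_means(c(50, 150, 300), 1.7316, 236.41, 2.097)
calibrate_group_means <- function(levels, slope, intercept, ratio) {
  levels <- as.numeric(levels)
  if (length(levels) != 3L || anyDuplicated(levels)) {
    stop("`levels` must be 3 distinct values", call. = FALSE)
  }
  if (is.unsorted(levels)) stop("`levels` must be increasing", call. = FALSE)
  if (!is.finite(ratio) || ratio <= 0) stop("`ratio` must be > 0", call. = FALSE)
  lbar <- mean(levels)
  sxx <- sum((levels - lbar)^2)
  a <- rbind(
    (levels - lbar) / sxx,       # OLS slope functional
    rep(1 / 3, 3L),              # mean level -> intercept via mu_bar
    c(-ratio, 0, 1)              # ratio constraint
  )
  b <- c(slope, intercept + slope * lbar, 0)
  mu <- tryCatch(solve(a, b), error = function(e) {
    stop("calibration-infeasible error: singular constraint system",
         call. = FALSE)
  })
  if (any(mu <= 0)) {
    warning("calibrated group mean(s) not strictly positive")
  }
  names(mu) <- as.character(levels)
  mu
}

#' One-factor loadings reproducing a correlation triple
#'
#' Closed-form loadings for a single-common-factor model whose pairwise
#' products reproduce the target correlations:
#' `w_x = sqrt(rho_xy * rho_xz / rho_yz)`, `w_y = rho_xy / w_x`,
#' `w_z = rho_xz / w_x`.
#'
#' @param rho_xy,rho_xz,rho_yz Target pairwise correlations in (0, 1].
#' @return Named numeric vector `c(w_x, w_y, w_z)`, each in (0, 1].
#' @export
#' @examples
#' factor_loadings(0.93, 0.88, 0.91)
factor_loadings <- function(rho_xy, rho_xz, rho_yz) {
  rho <- c(rho_xy = rho_xy, rho_xz = rho_xz, rho_yz = rho_yz)
  if (any(!is.finite(rho)) || any(rho <= 0) || any(rho > 1)) {
    stop("correlation targets must lie in (0, 1]", call. = FALSE)
  }
  w_x <- sqrt(rho_xy * rho_xz / rho_yz)
  w <- c(w_x = w_x, w_y = rho_xy / w_x, w_z = rho_xz / w_x)
  if (any(w > 1 + 1e-12)) {
    bad <- names(w)[which.max(w)]
    stop(sprintf(
      "infeasible correlation triple: loading %s = %.4f exceeds 1", bad,
      max(w)), call. = FALSE)
  }
  pmin(w, 1)
}

#' Expected envelope peak time as a function of feed rate
#'
#' Faster feed delivery concentrates the feeding burst earlier: the envelope
#' peak time declines linearly with feed rate, anchored at the observed
#' ~35 s peak for 1 g/s and ~20 s peak for 3 g/s, and clamped away from the
#' trial boundaries.
#'
#' @param feed_rate Feed delivery rate V in g/s (> 0).
#' @param coeffs Numeric `c(intercept, slope)` in seconds and s per (g/s);
#'   default `c(42.5, -7.5)`.
#' @param duration_s Trial length in s, used for clamping to
#'   `[5, duration_s - 5]`.
#' @return Peak time in seconds.
#' @export
#' @examples
#' peak_time_model(3)  # 20 s
#' peak_time_model(1)  # 35 s
peak_time_model <- function(feed_rate, coeffs = c(42.5, -7.5),
                            duration_s = 120) {
  if (any(feed_rate <= 0)) stop("`feed_rate` must be > 0", call. = FALSE)
  tp <- coeffs[1] + coeffs[2] * feed_rate
  pmin(pmax(tp, 5), max(duration_s - 5, 5))
}

#' Calibration profile for one single-factor experiment
#'
#' Bundles the calibrated group means of one experiment (size or density)
#' with the published line they refit to and the baseline values of the
#' factors held fixed in that experiment.
#'
#' @param levels,slope,intercept,ratio Passed to [calibrate_group_means()].
#' @param factor Name of the varied factor (`"size_g"` or `"density"`).
#' @param baseline Named list of the fixed factor values for the experiment.
#' @return Object of class `"calibration_profile"`.
#' @export
calibration_profile <- function(levels, slope, intercept, ratio, factor,
                                baseline) {
  means <- calibrate_group_means(levels, slope, intercept, ratio)
  structure(list(levels = as.numeric(levels), means = unname(means),
                 slope = slope, intercept = intercept, ratio = ratio,
                 factor = factor, baseline = baseline),
            class = "calibration_profile")
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat(sprintf("Calibration profile (%s): levels %s -> means %s um\n",
              x$factor, paste(x$levels, collapse = "/"),
              paste(sprintf("%.2f", x$means), collapse = "/")))
  cat(sprintf("  refits to Y = %.4f * %s + %.2f, top/bottom ratio %.3f\n",
              x$slope, x$factor, x$intercept, x$ratio))
  invisible(x)
}

#' Default calibration profiles
#'
#' The size experiment (50/150/300 g at 30 fish, 1 g/s, 5 mm pellets) refits
#' to `Y = 1.7316 S + 236.41` with a 109.7 percent top-vs-bottom increase;
#' the density experiment (20/40/60 fish at 50 g, 1 g/s, 5 mm pellets)
#' refits to `Y = 5.4250 D + 47.11` with a 141.9 percent increase.
#'
#' @return Named list of two [calibration_profile()] objects, `size` and
#'   `density`.
#' @export
default_profiles <- function() {
  list(
    size = calibration_profile(
      levels = c(50, 150, 300), slope = 1.7316, intercept = 236.41,
      ratio = 2.097, factor = "size_g",
      baseline = list(density = 30, feed_rate = 1, pellet_mm = 5)),
    density = calibration_profile(
      levels = c(20, 40, 60), slope = 5.4250, intercept = 47.11,
      ratio = 2.419, factor = "density",
      baseline = list(size_g = 50, feed_rate = 1, pellet_mm = 5))
  )
}

# piecewise-linear interpolation through (levels, means) with linear
# extrapolation on the edge segments, clamped to +-50% of the level range
.profile_interp <- function(profile, x) {
  lv <- profile$levels
  mu <- profile$means
  lo <- min(lv) * 0.5
  hi <- max(lv) * 1.5
  if (x < lo || x > hi) {
    warning(sprintf(
      "level %g outside +-50%% of calibrated range [%g, %g]; clamped",
      x, min(lv), max(lv)))
    x <- min(max(x, lo), hi)
  }
  if (x <= lv[1]) {
    s <- (mu[2] - mu[1]) / (lv[2] - lv[1])
    return(mu[1] + s * (x - lv[1]))
  }
  if (x >= lv[3]) {
    s <- (mu[3] - mu[2]) / (lv[3] - lv[2])
    return(mu[3] + s * (x - lv[3]))
  }
  approx(lv, mu, xout = x)$y
}

.matches_baseline <- function(config, profile) {
  bl <- profile$baseline
  all(vapply(names(bl), function(nm) {
    isTRUE(all.equal(config[[nm]], bl[[nm]]))
  }, logical(1)))
}

#' Expected peak window displacement for a trial condition
#'
#' When the condition matches an experiment's baseline exactly, the expected
#' peak is read (with linear interpolation across levels) from that
#' experiment's calibrated profile. Otherwise the two profiles are combined
#' multiplicatively after normalizing each to the reference condition
#' (S = 50 g, D = 30 fish, V = 1 g/s, 5 mm pellets); feed rate and pellet
#' size shift timing and oscillation frequency, not peak amplitude.
#'
#' @param config A [trial_config()].
#' @param profiles Profiles as returned by [default_profiles()].
#' @return Expected maximum 5-s window sum (um).
#' @export
#' @examples
#' mean_peak(trial_config(size_g = 300, density = 30, feed_rate = 1))
mean_peak <- function(config, profiles = default_profiles()) {
  stopifnot(inherits(config, "trial_config"))
  if (.matches_baseline(config, profiles$size)) {
    return(.profile_interp(profiles$size, config$size_g))
  }
  if (.matches_baseline(config, profiles$density)) {
    return(.profile_interp(profiles$density, config$density))
  }
  mu0 <- .profile_interp(profiles$size, 50)
  g_s <- .profile_interp(profiles$size, config$size_g) / mu0
  g_d <- .profile_interp(profiles$density, config$density) /
    .profile_interp(profiles$density, 30)
  mu0 * g_s * g_d
}
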