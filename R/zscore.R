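# Z-score normalization with explicit fit/apply/invert stages so that
# statistics are always fitted on training data only and predictions can be
# reported back on the original um scale.

#' Fit z-score normalization statistics
#'
#' Computes per-column mean and sample (n-1) standard deviation of a feature
#' matrix. By default a zero-variance feature is an error (silently dividing
#' by zero would poison downstream training); `constant_ok = TRUE` records a
#' unit scale for such features instead, so they are centred but not scaled —
#' needed when static trial covariates are constant within a dataset.
#'
#' @param x Numeric matrix (rows = observations) or vector.
#' @param constant_ok Treat zero-sd columns as scale 1 instead of erroring.
#' @return An object of class `"zscore_stats"` with `mean` and `sd` vectors.
#' @export
#' @examples
#' zscore_fit(cbind(a = 1:3, b = c(2, 4, 9)))
zscore_fit <- function(x, constant_ok = FALSE) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdev <- apply(x, 2L, sd)
  zero <- sdev == 0 | !is.finite(sdev)
  if (any(zero)) {
    if (!constant_ok) {
      stop("degenerate-feature error: zero standard deviation in column(s) ",
           paste(which(zero), collapse = ", "), call. = FALSE)
    }
    sdev[zero] <- 1
  }
  structure(list(mean = mu, sd = sdev, constant = zero),
            class = "zscore_stats")
}

#' Apply or invert fitted z-score statistics
#'
#' @param x Numeric matrix or vector conformable with the fitted statistics.
#' @param stats A `"zscore_stats"` object from [zscore_fit()].
#' @return Matrix of the same shape as `x`.
#' @export
zscore_apply <- function(x, stats) {
  stopifnot(inherits(stats, "zscore_stats"))
  x <- as.matrix(x)
  sweep(sweep(x, 2L, stats$mean, "-"), 2L, stats$sd, "/")
}

#' @rdname zscore_apply
#' @export
zscore_invert <- function(x, stats) {
  stopifnot(inherits(stats, "zscore_stats"))
  x <- as.matrix(x)
  sweep(sweep(x, 2L, stats$sd, "*"), 2L, stats$mean, "+")
}

#' One-shot z-score normalization
#'
#' Convenience wrapper: fits statistics on `x` (or reuses supplied `stats`)
#' and returns the normalized matrix together with the statistics used.
#'
#' @inheritParams zscore_fit
#' @param stats Optional pre-fitted `"zscore_stats"`; when supplied, `x` is
#'   normalized with them instead of refitting.
#' @return List with `x` (normalized matrix) and `stats`.
#' @export
zscore_normalize <- function(x, stats = NULL, constant_ok = FALSE) {
  if (is.null(stats)) stats <- zscore_fit(x, constant_ok = constant_ok)
  list(x = zscore_apply(x, stats), stats = stats)
}
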