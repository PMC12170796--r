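#' Round a smile-intensity series to whole numbers
#'
#' Facial-expression intensity estimates arrive as fractional values on a
#' 0--100 scale; rounding to whole numbers suppresses sub-integer jitter
#' before smoothing. Halves round away from zero (0.5 becomes 1), matching
#' the convention of common spreadsheet tools rather than base R's
#' round-half-even.
#'
#' @param x Numeric vector of intensities.
#' @return Numeric vector of integers, same length and bounds.
#' @export
#' @examples
#' round_to_integers(c(0.4, 0.5, 99.6))
round_to_integers <- function(x) {
  stopifnot(is.numeric(x))
  round_half_away(x)
}

#' Centred rolling-mean smoothing
#'
#' Applies a centred moving average of `window_samples` samples (160 ms at
#' 25 Hz corresponds to four samples), emphasising real expression changes
#' over frame noise. Output length equals input length: windows shrink at
#' the series edges instead of trimming them, so smoothed pairs stay aligned
#' for correlation. For even window sizes the window at position `i` covers
#' `i - floor((w-1)/2)` through `i + floor(w/2)` (one extra sample on the
#' right), the convention of `zoo::rollapply(..., align = "center")`.
#'
#' Implemented with cumulative sums so smoothing thousands of series stays
#' cheap; equality with `zoo::rollapply(..., partial = TRUE)` is pinned in
#' the test suite.
#'
#' @param x Numeric vector.
#' @param window_samples Window length in samples (>= 1, <= length(x)).
#' @return Numeric vector, same length as `x`.
#' @export
#' @examples
#' smooth_rolling_mean(c(0, 0, 4, 0, 0), 4)
smooth_rolling_mean <- function(x, window_samples) {
  stopifnot(is.numeric(x))
  if (length(x) == 0) stop("cannot smooth an empty series")
  w <- as.integer(window_samples)
  stopifnot(w >= 1, w <= length(x))
  if (w == 1) return(as.numeric(x))
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(i - (w - 1L) %/% 2L, 1L)
  hi <- pmin(i + w %/% 2L, n)
  s <- c(0, cumsum(x))
  (s[hi + 1L] - s[lo]) / (hi - lo + 1L)
}

#' Autoregressive prewhitening
#'
#' Continuous physiological signals such as heart rate carry strong
#' autocorrelation (slow cyclic fluctuations, arousal trends) that inflates
#' the correlation between any two smooth series. Prewhitening fits an AR
#' model to the demeaned series -- Yule--Walker coefficients, order selected
#' by AIC over `0..max_order` -- and replaces the series by its one-step-ahead
#' prediction errors, whose cross-correlation then reflects moment-to-moment
#' covariation rather than shared smoothness.
#'
#' @param x Numeric vector, length at least `max_order + 2`.
#' @param max_order Maximum AR order considered by AIC; defaults to
#'   `floor(10 * log10(length(x)))`, the convention of [stats::ar()].
#' @return A list with `residuals` (numeric, length `length(x) - order`;
#'   element `k` is the prediction error at time `order + k`), `fit` (a list
#'   with `order`, `coefficients`, `innovation_variance`, `mean`) and
#'   `start_index` (time index of the first residual). Order 0 yields the
#'   demeaned series.
#' @export
#' @examples
#' set.seed(1)
#' pw <- prewhiten_ar(as.numeric(arima.sim(list(ar = 0.7), 80)))
#' pw$fit$order
prewhiten_ar <- function(x, max_order = NULL) {
  stopifnot(is.numeric(x))
  if (is.null(max_order)) max_order <- floor(10 * log10(length(x)))
  max_order <- as.integer(max_order)
  stopifnot(max_order >= 0)
  if (length(x) < max_order + 2) {
    stop("series too short for max_order = ", max_order)
  }
  if (stats::var(x) == 0) stop("zero variance, cannot prewhiten")

  if (max_order == 0) {
    res <- x - mean(x)
    fit <- list(order = 0L, coefficients = numeric(0),
                innovation_variance = stats::var(res), mean = mean(x))
    return(list(residuals = res, fit = fit, start_index = 1L))
  }

  a <- stats::ar(x, aic = TRUE, order.max = max_order,
                 method = "yule-walker", demean = TRUE)
  ord <- a$order
  if (ord == 0) {
    res <- x - mean(x)
  } else {
    res <- as.numeric(a$resid)[(ord + 1):length(x)]
  }
  fit <- list(
    order = as.integer(ord),
    coefficients = as.numeric(a$ar),
    innovation_variance = as.numeric(a$var.pred),
    mean = as.numeric(a$x.mean)
  )
  list(residuals = res, fit = fit, start_index = ord + 1L)
}

#' Preprocess one smile series
#'
#' The canonical smile pipeline: integer rounding followed by a short
#' centred rolling mean (four samples, 160 ms at 25 Hz).
#'
#' @param x Numeric smile-intensity vector.
#' @param smooth_samples Smoothing window in samples.
#' @return Numeric vector, same length.
#' @export
prep_smile <- function(x, smooth_samples = 4) {
  smooth_rolling_mean(round_to_integers(x), smooth_samples)
}
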