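#' Windowed cross-lagged correlation (WCLC)
#'
#' Slides a fixed window along the pair of series and, within each window,
#' correlates the two members across a symmetric grid of temporal lags,
#' recording the maximum correlation over lags ("peak synchrony") and the
#' lag at which it occurs. Allowing lags captures delayed responding and
#' shifts in leader-follower dynamics: sometimes A smiles first and B
#' follows, sometimes vice versa. Positive `peak_lag_s` means member B's
#' signal follows member A's.
#'
#' The smile-study grid is a 60-s window (1500 samples at 25 Hz) moving in
#' 1-s (25-sample) increments with lags up to +/- 1 s in 1-sample (0.04 s)
#' steps; the heart-rate grid is a 60-s window moving in 2-s (one-sample)
#' steps with lags up to +/- 2 s (one sample).
#'
#' A lag whose overlapping slices have zero variance is undefined and
#' skipped; the window's peak is undefined only if every lag is. When every
#' defined lag gives a negative correlation the signed maximum is still
#' recorded and the window flagged `all_negative` rather than dropped, which
#' would bias time courses.
#'
#' @param a,b Numeric series of equal length.
#' @param rate_hz Sampling rate in Hz.
#' @param window_s Window length in seconds.
#' @param step_s Window step in seconds.
#' @param max_lag_s Maximum absolute lag in seconds.
#' @param lag_step_samples Lag grid spacing in samples.
#' @param method Correlation method, `"pearson"` or `"spearman"`.
#'
#' @return A tibble with one row per window: `window_start_s`, `peak_r`,
#'   `peak_lag_s`, `all_negative`; the grid configuration is echoed in the
#'   `"wclc_config"` attribute.
#' @export
#' @examples
#' x <- sin(seq(0, 24 * pi, length.out = 600))
#' w <- wclc(x, x, rate_hz = 5, window_s = 60, step_s = 10, max_lag_s = 1)
#' all(w$peak_r == 1)
wclc <- function(a, b, rate_hz, window_s = 60, step_s = 1, max_lag_s = 1,
                 lag_step_samples = 1L, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(a) == length(b), rate_hz > 0)
  n <- length(a)
  W <- samples_or_stop(window_s, rate_hz, "window_s")
  S <- samples_or_stop(step_s, rate_hz, "step_s")
  L <- samples_or_stop(max_lag_s, rate_hz, "max_lag_s")
  lag_step <- as.integer(lag_step_samples)
  stopifnot(W >= 2, S >= 1, L >= 0, lag_step >= 1)
  if (W > n) stop("window (", W, " samples) exceeds series length ", n)

  pos <- if (L >= lag_step) seq(lag_step, L, by = lag_step) else integer(0)
  lags <- c(-rev(pos), 0L, pos)
  starts <- seq(1L, n - W + 1L, by = S)

  peak_r <- rep(NA_real_, length(starts))
  peak_lag <- rep(NA_real_, length(starts))
  all_neg <- rep(NA, length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    aw <- a[s:(s + W - 1L)]
    bw <- b[s:(s + W - 1L)]
    rs <- vapply(lags, function(l) lagged_correlation(aw, bw, l, method),
                 numeric(1))
    if (all(is.na(rs))) next
    top <- max(rs, na.rm = TRUE)
    cand <- which(!is.na(rs) & rs == top)
    # tie-break: smallest |lag|, then negative before positive
    cand <- cand[order(abs(lags[cand]), lags[cand])]
    peak_r[i] <- top
    peak_lag[i] <- lags[cand[1]] / rate_hz
    all_neg[i] <- top < 0
  }

  out <- tibble::tibble(
    window_start_s = (starts - 1L) / rate_hz,
    peak_r = peak_r,
    peak_lag_s = peak_lag,
    all_negative = all_neg
  )
  attr(out, "wclc_config") <- list(
    rate_hz = rate_hz, window_s = window_s, step_s = step_s,
    max_lag_s = max_lag_s, lag_step_samples = lag_step,
    window_samples = W, step_samples = S, max_lag_samples = L,
    lag_step_s = lag_step / rate_hz, method = method
  )
  out
}

# Seconds-to-samples conversion that insists on an integer sample count.
samples_or_stop <- function(seconds, rate_hz, what) {
  x <- seconds * rate_hz
  if (abs(x - round(x)) > 1e-8) {
    stop(what, " = ", seconds, " s is not an integer number of samples at ",
         rate_hz, " Hz")
  }
  as.integer(round(x))
}

#' Mean peak-synchrony time course
#'
#' Aggregates per-pair WCLC peaks into a mean time course per
#' condition x pair-type group with 95% confidence intervals, the summary
#' plotted to compare real pairs against the pseudo-pair null across the
#' exercise.
#'
#' @param results A tibble of stacked [wclc()] outputs with columns
#'   `pair_id`, `condition`, `pair_type`, `window_start_s`, `peak_r`.
#' @return A tibble with `condition`, `pair_type`, `window_start_s`,
#'   `mean_peak_r`, `ci_halfwidth` (`1.96 * SE`; `NA` when fewer than two
#'   defined pairs) and `n_pairs` (pairs with a defined peak at that
#'   window).
#' @export
peak_timecourse <- function(results) {
  needed <- c("pair_id", "condition", "pair_type", "window_start_s", "peak_r")
  stopifnot(all(needed %in% names(results)))
  grids <- results |>
    dplyr::group_by(.data$condition, .data$pair_type, .data$pair_id) |>
    dplyr::summarise(
      grid = paste(sort(unique(.data$window_start_s)), collapse = ","),
      .groups = "drop"
    )
  if (length(unique(grids$grid)) > 1) {
    stop("mixed window grids across pairs; recompute WCLC on one grid")
  }
  results |>
    dplyr::group_by(.data$condition, .data$pair_type, .data$window_start_s) |>
    dplyr::summarise(
      mean_peak_r = mean(.data$peak_r, na.rm = TRUE),
      n_pairs = sum(!is.na(.data$peak_r)),
      ci_halfwidth = ifelse(
        n_pairs >= 2,
        1.96 * stats::sd(.data$peak_r, na.rm = TRUE) / sqrt(n_pairs),
        NA_real_
      ),
      .groups = "drop"
    ) |>
    dplyr::select("condition", "pair_type", "window_start_s",
                  "mean_peak_r", "ci_halfwidth", "n_pairs")
}
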