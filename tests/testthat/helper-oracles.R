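# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: textbook formulas and exhaustive loops only.

# Pearson correlation from the textbook sum formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# Centered moving average with edge shrinkage, written as an explicit loop
# from the documented contract: window at i covers
# i - floor((w-1)/2) .. i + floor(w/2), clipped to the series.
oracle_rolling_mean <- function(x, w) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - floor((w - 1) / 2))
    hi <- min(n, i + floor(w / 2))
    out[i] <- mean(x[lo:hi])
  }
  out
}

# Exhaustive double loop over windows and lags; peak = max defined
# correlation, ties broken by smallest |lag| then negative before positive.
oracle_wclc <- function(a, b, rate_hz, window_s, step_s, max_lag_s,
                        lag_step_samples) {
  n <- length(a)
  W <- as.integer(round(window_s * rate_hz))
  S <- as.integer(round(step_s * rate_hz))
  L <- as.integer(round(max_lag_s * rate_hz))
  lags <- seq(-L, L, by = lag_step_samples)
  starts <- seq(1L, n - W + 1L, by = S)
  peak_r <- rep(NA_real_, length(starts))
  peak_lag <- rep(NA_real_, length(starts))
  for (wi in seq_along(starts)) {
    s <- starts[wi]
    aw <- a[s:(s + W - 1)]
    bw <- b[s:(s + W - 1)]
    best_r <- -Inf
    best_lag <- NA_real_
    for (l in lags) {
      if (l >= 0) {
        xs <- aw[1:(W - l)]
        ys <- bw[(1 + l):W]
      } else {
        xs <- aw[(1 - l):W]
        ys <- bw[1:(W + l)]
      }
      if (stats::var(xs) == 0 || stats::var(ys) == 0) next
      r <- oracle_pearson(xs, ys)
      better <- r > best_r ||
        (r == best_r && (abs(l) < abs(best_lag) ||
                           (abs(l) == abs(best_lag) && l < best_lag)))
      if (better) {
        best_r <- r
        best_lag <- l
      }
    }
    if (is.finite(best_r)) {
      peak_r[wi] <- best_r
      peak_lag[wi] <- best_lag / rate_hz
    }
  }
  list(window_start_s = (starts - 1) / rate_hz, peak_r = peak_r,
       peak_lag_s = peak_lag)
}

# Small default config for fast dyad simulation in tests.
tiny_cfg <- function(...) {
  args <- list(n_participants = 4, n_rounds = 1, conditions = "gazing",
               duration_s = 40)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
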