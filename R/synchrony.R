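#' Lagged correlation between two equal-rate series
#'
#' Correlates `a[t]` with `b[t + lag]` over the overlapping range: a
#' positive lag means member B's signal follows member A's. This is the
#' primitive behind both global synchrony (lag 0) and the windowed
#' cross-lagged analysis.
#'
#' @param a,b Numeric vectors of equal length.
#' @param lag_samples Signed integer lag in samples, `|lag| < length`.
#' @param method `"pearson"` or `"spearman"` (Pearson on average ranks).
#' @return The correlation, or `NA` if either overlapping slice has zero
#'   variance.
#' @export
#' @examples
#' lagged_correlation(sin(1:100), sin(1:100 + 3), lag_samples = 3)
lagged_correlation <- function(a, b, lag_samples = 0L,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(a) == length(b))
  n <- length(a)
  k <- as.integer(lag_samples)
  if (abs(k) >= n) stop("|lag_samples| must be smaller than the series length")
  if (k >= 0) {
    av <- a[seq_len(n - k)]
    bv <- b[seq_len(n - k) + k]
  } else {
    av <- a[seq_len(n + k) - k]
    bv <- b[seq_len(n + k)]
  }
  cor_defined(av, bv, method)
}

# Correlation that returns NA (not a warning) on zero-variance slices.
cor_defined <- function(x, y, method) {
  if (method == "spearman") {
    x <- rank(x, ties.method = "average")
    y <- rank(y, ties.method = "average")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Global synchrony of one (pseudo-)pair
#'
#' The overall synchrony measure: the correlation between the two members'
#' full preprocessed series at lag zero, together with the per-member and
#' dyad mean signal levels used as covariates downstream.
#'
#' @param a,b Preprocessed numeric series of equal length.
#' @param method `"pearson"` (reflecting actual signal intensity) or
#'   `"spearman"` (rank-based robustness variant).
#' @param prewhitened Flag recorded in the output: were the inputs AR
#'   residuals?
#' @param pair_id,condition,pair_type Metadata carried into the record.
#' @return A one-row tibble: `pair_id`, `condition`, `pair_type`, `method`,
#'   `prewhitened`, `r`, `mean_a`, `mean_b`, `mean_pair`, `n_samples`,
#'   `eligible`, `exclusion_reason`.
#' @export
global_synchrony <- function(a, b, method = c("pearson", "spearman"),
                             prewhitened = FALSE, pair_id = NA_character_,
                             condition = NA_character_,
                             pair_type = NA_character_) {
  method <- match.arg(method)
  if (length(a) != length(b)) {
    stop("members' series have different lengths (", length(a), " vs ",
         length(b), ")")
  }
  r <- lagged_correlation(a, b, 0L, method)
  eligible <- !is.na(r)
  tibble::tibble(
    pair_id = pair_id,
    condition = condition,
    pair_type = pair_type,
    method = method,
    prewhitened = prewhitened,
    r = r,
    mean_a = mean(a),
    mean_b = mean(b),
    mean_pair = (mean(a) + mean(b)) / 2,
    n_samples = length(a),
    eligible = eligible,
    exclusion_reason = if (eligible) NA_character_ else "zero variance"
  )
}

#' Smiling-synchrony eligibility
#'
#' Smiling synchrony can only be evaluated where both participants smiled at
#' some point during the exercise; if at least one member never smiled the
#' dyad is excluded. The check runs on the raw (pre-smoothing) series.
#'
#' @param a_raw,b_raw Raw smile-intensity vectors.
#' @return A list with `eligible` (logical) and `reason` (`NA` or a label
#'   naming the non-smiling member side).
#' @export
#' @examples
#' smile_eligibility(c(0, 0, 3), c(0, 1, 0))$eligible
smile_eligibility <- function(a_raw, b_raw) {
  a_smiled <- max(a_raw) > 0
  b_smiled <- max(b_raw) > 0
  if (a_smiled && b_smiled) {
    list(eligible = TRUE, reason = NA_character_)
  } else {
    who <- c("a", "b")[!c(a_smiled, b_smiled)]
    list(eligible = FALSE,
         reason = paste0("non-smiler: member ", paste(who, collapse = "+")))
  }
}
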