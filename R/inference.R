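#' Standardize a ratings measure
#'
#' Pre/post measures are scaled relative to their pre-exercise mean and SD
#' (pooled across conditions, or within condition with `by_condition`), so
#' that the two timepoints stay on a common scale and post-pre changes read
#' as pre-exercise SD units. Measures without pre values are z-scored by
#' their own mean and SD.
#'
#' @param ratings Long ratings tibble (see [simulate_outcomes()]).
#' @param measure Measure name to standardize.
#' @param by_condition Scale within each condition instead of pooling.
#' @return The ratings tibble with that measure's `pre`/`post` replaced by
#'   standardized values; scaling constants are recorded in the
#'   `"scaling"` attribute.
#' @export
standardize <- function(ratings, measure, by_condition = FALSE) {
  stopifnot(measure %in% ratings$measure)
  idx <- ratings$measure == measure
  groups <- if (by_condition) ratings$condition[idx] else rep("all", sum(idx))
  scalings <- list()
  for (g in unique(groups)) {
    gi <- which(idx)[groups == g]
    pre <- ratings$pre[gi]
    if (any(!is.na(pre))) {
      mu <- mean(pre, na.rm = TRUE)
      sdv <- stats::sd(pre, na.rm = TRUE)
      if (is.na(sdv) || sdv == 0) {
        stop("zero pre-exercise SD for measure '", measure, "'")
      }
      ratings$pre[gi] <- (ratings$pre[gi] - mu) / sdv
      ratings$post[gi] <- (ratings$post[gi] - mu) / sdv
    } else {
      mu <- mean(ratings$post[gi], na.rm = TRUE)
      sdv <- stats::sd(ratings$post[gi], na.rm = TRUE)
      if (is.na(sdv) || sdv == 0) {
        stop("zero SD for measure '", measure, "'")
      }
      ratings$post[gi] <- (ratings$post[gi] - mu) / sdv
    }
    scalings[[g]] <- c(mean = mu, sd = sdv)
  }
  attr(ratings, "scaling") <- c(attr(ratings, "scaling"),
                                stats::setNames(list(scalings), measure))
  ratings
}

#' Dyad-level change scores
#'
#' Collapses rater-level pre/post ratings to one change score per dyad and
#' measure: post minus pre, averaged across the two dyad members. Post-only
#' measures (e.g. the dictator allocation) yield the members' mean value
#' instead. Dyads with a missing member record are excluded and listed in
#' the `"excluded"` attribute.
#'
#' @param ratings Long ratings tibble.
#' @return A tibble with `dyad_id`, `condition`, `round`, `measure`,
#'   `change` (or mean value for post-only measures), `n_members`.
#' @export
dyad_change_scores <- function(ratings) {
  per <- ratings |>
    dplyr::mutate(value = ifelse(is.na(.data$pre), .data$post,
                                 .data$post - .data$pre)) |>
    dplyr::group_by(.data$dyad_id, .data$condition, .data$round,
                    .data$measure) |>
    dplyr::summarise(change = mean(.data$value),
                     n_members = dplyr::n(), .groups = "drop")
  ok <- per$n_members == 2 & !is.na(per$change)
  out <- per[ok, , drop = FALSE]
  attr(out, "excluded") <- per[!ok, c("dyad_id", "measure")]
  out
}

#' Ordinary least squares with classical inference
#'
#' Closed-form least-squares fit for the dyad-level models (synchrony and
#' outcome-change regressions): normal-equation estimates via the QR
#' decomposition, classical standard errors, and two-sided t p-values on
#' n - k degrees of freedom. Factors are dummy-coded through
#' [stats::model.matrix()], so reference conditions follow the factor level
#' ordering of the data.
#'
#' @param formula Model formula.
#' @param data Data frame.
#' @return A `model_fit` tibble with `term`, `estimate`, `se`, `statistic`,
#'   `df`, `p_value`; attributes `n`, `sigma`, `r_squared`, `descriptor`.
#'   A residual variance that is numerically zero is flagged in the
#'   `"zero_residual"` attribute rather than reporting the zero SEs as
#'   meaningful.
#' @export
#' @examples
#' fit_ols(mpg ~ wt + cyl, mtcars)
fit_ols <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- nrow(X)
  k <- ncol(X)
  qx <- qr(X)
  if (qx$rank < k) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):k]]
    stop("rank-deficient design; collinear terms: ",
         paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  resid <- y - X %*% beta
  df <- n - k
  if (df <= 0) stop("no residual degrees of freedom (n = ", n, ", k = ", k, ")")
  rss <- sum(resid^2)
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  tval <- as.numeric(beta) / se
  out <- tibble::tibble(
    term = colnames(X),
    estimate = as.numeric(beta),
    se = as.numeric(se),
    statistic = tval,
    df = df,
    p_value = 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  )
  tss <- sum((y - mean(y))^2)
  attr(out, "n") <- n
  attr(out, "sigma") <- sqrt(sigma2)
  attr(out, "r_squared") <- if (tss > 0) 1 - rss / tss else NA_real_
  attr(out, "descriptor") <- paste("ols:", paste(deparse(formula), collapse = ""))
  attr(out, "zero_residual") <- sigma2 < 1e-20
  class(out) <- c("model_fit", class(out))
  out
}

#' Pair versus pseudo-pair t-tests with Bonferroni correction
#'
#' A series of independent two-sample t-tests comparing synchrony between
#' real pairs and pseudo pairs within each condition, and between conditions
#' among real pairs, with a Bonferroni-corrected per-test threshold
#' `alpha / m`. Pooled-variance (Student) tests are the default, matching
#' the `df = n1 + n2 - 2` reporting convention of such comparisons; Welch
#' tests are available by flag.
#'
#' @param sync_table Synchrony records ([synchrony_table()]); ineligible
#'   rows (undefined `r`) are dropped.
#' @param comparisons A named list of contrasts, each a list with elements
#'   `arm1` and `arm2`, themselves lists with `condition` and `pair_type`
#'   filters. `NULL` builds the standard six contrasts from the conditions
#'   present: within-condition real vs pseudo, plus all between-condition
#'   comparisons among real pairs.
#' @param alpha Family-wise error rate (default 0.05).
#' @param var_equal Pooled-variance Student t (default) or Welch.
#' @return A tibble with `contrast`, `mean1`, `mean2`, `n1`, `n2`,
#'   `statistic`, `df`, `p_value`, `threshold` (`alpha / m`) and
#'   `significant` (corrected).
#' @export
pair_vs_pseudo_tests <- function(sync_table, comparisons = NULL,
                                 alpha = 0.05, var_equal = TRUE) {
  if (is.null(comparisons)) comparisons <- default_contrasts(sync_table)
  m <- length(comparisons)
  stopifnot(m >= 1)
  threshold <- alpha / m

  arm_values <- function(spec) {
    keep <- rep(TRUE, nrow(sync_table))
    if (!is.null(spec$condition)) {
      keep <- keep & sync_table$condition == spec$condition
    }
    if (!is.null(spec$pair_type)) {
      keep <- keep & sync_table$pair_type == spec$pair_type
    }
    sync_table$r[keep & !is.na(sync_table$r)]
  }

  rows <- lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    x1 <- arm_values(cmp$arm1)
    x2 <- arm_values(cmp$arm2)
    if (length(x1) < 2 || length(x2) < 2) {
      stop("contrast '", nm, "' has an arm with fewer than 2 observations")
    }
    tt <- stats::t.test(x1, x2, var.equal = var_equal)
    tibble::tibble(
      contrast = nm,
      mean1 = mean(x1), mean2 = mean(x2),
      n1 = length(x1), n2 = length(x2),
      statistic = unname(tt$statistic),
      df = unname(tt$parameter),
      p_value = tt$p.value
    )
  })
  out <- dplyr::bind_rows(rows)
  out$threshold <- threshold
  out$significant <- out$p_value < threshold
  out
}

# The standard six-contrast family: real vs pseudo within each condition,
# and all pairwise condition comparisons among real pairs.
default_contrasts <- function(sync_table) {
  conds <- sort(unique(sync_table$condition))
  out <- list()
  for (cc in conds) {
    out[[paste0(cc, ": real vs pseudo")]] <- list(
      arm1 = list(condition = cc, pair_type = "real"),
      arm2 = list(condition = cc, pair_type = "pseudo")
    )
  }
  if (length(conds) >= 2) {
    combos <- utils::combn(conds, 2)
    for (k in seq_len(ncol(combos))) {
      c1 <- combos[1, k]; c2 <- combos[2, k]
      out[[paste0(c1, " vs ", c2, " (real)")]] <- list(
        arm1 = list(condition = c1, pair_type = "real"),
        arm2 = list(condition = c2, pair_type = "real")
      )
    }
  }
  out
}
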