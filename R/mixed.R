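#' Dyadic mixed model with random-intercept pruning
#'
#' Multilevel model for dyadic data: the requested fixed effects plus random
#' intercepts for any of participant, dyad, partner and round, fitted by
#' REML (lme4 via lmerTest for Satterthwaite degrees of freedom). Repeated
#' participation across rounds and the two-members-per-dyad structure make
#' observations non-independent; the random intercepts absorb those
#' dependencies.
#'
#' When the full random structure is degenerate (singular fit: some variance
#' component estimated at zero), the worst-performing random intercept --
#' the one with the smallest estimated variance -- is removed and the model
#' refitted, repeating until the fit is non-singular or no random intercepts
#' remain, in which case the model collapses to OLS. The pruning path is
#' recorded rather than guessed at in advance.
#'
#' @param formula Fixed-effects formula (no random terms), e.g.
#'   `post ~ pre + condition`.
#' @param data Data frame containing the model variables and the grouping
#'   columns named in `random`.
#' @param random Character vector of grouping columns to receive random
#'   intercepts; subset of the columns of `data`, each needing at least two
#'   levels (factors with fewer are dropped up front with a note in the
#'   pruning path).
#' @return A `model_fit` tibble (fixed effects: `term`, `estimate`, `se`,
#'   `statistic`, `df`, `p_value`) with attributes `variance_components`,
#'   `pruning_path`, `random_retained`, `n`, `descriptor` and `engine`
#'   (`"lmer"` or `"ols"`).
#' @export
fit_dyadic_mixed <- function(formula, data,
                             random = c("participant", "dyad", "partner",
                                        "round")) {
  missing_cols <- setdiff(random, names(data))
  if (length(missing_cols)) {
    stop("grouping columns not in data: ", paste(missing_cols, collapse = ", "))
  }
  path <- character(0)
  # factors with fewer than two levels cannot carry a random intercept
  usable <- random[vapply(random, function(g) {
    length(unique(data[[g]])) >= 2
  }, logical(1))]
  dropped_upfront <- setdiff(random, usable)
  if (length(dropped_upfront)) {
    path <- c(path, paste0("dropped (single level): ",
                           paste(dropped_upfront, collapse = ", ")))
  }
  random <- usable

  fit <- NULL
  while (length(random) > 0) {
    rf <- paste(sprintf("(1 | %s)", random), collapse = " + ")
    full <- stats::as.formula(
      paste(deparse(formula[[2]]), "~",
            paste(deparse(formula[[3]]), collapse = ""), "+", rf)
    )
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lmerTest::lmer(full, data = data, REML = TRUE)
      )),
      error = function(e) e
    )
    failed <- inherits(fit, "error")
    singular <- !failed && lme4::isSingular(fit, tol = 1e-5)
    if (!failed && !singular) break
    # prune the worst-performing random intercept (smallest variance; on
    # outright failure, drop the last-listed factor)
    worst <- if (failed) {
      random[length(random)]
    } else {
      vc <- as.data.frame(lme4::VarCorr(fit))
      vc <- vc[vc$grp != "Residual", ]
      vc$grp[which.min(vc$vcov)]
    }
    path <- c(path, paste0("pruned: ", worst,
                           if (failed) " (fit failure)" else " (variance ~ 0)"))
    random <- setdiff(random, worst)
    fit <- NULL
  }

  if (is.null(fit) || inherits(fit, "error")) {
    path <- c(path, "collapsed to OLS (no usable random intercepts)")
    out <- fit_ols(formula, data)
    attr(out, "variance_components") <- NULL
    attr(out, "pruning_path") <- path
    attr(out, "random_retained") <- character(0)
    attr(out, "engine") <- "ols"
    return(out)
  }

  cf <- stats::coef(summary(fit))
  out <- tibble::tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    se = cf[, "Std. Error"],
    statistic = cf[, "t value"],
    df = cf[, "df"],
    p_value = cf[, "Pr(>|t|)"]
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  attr(out, "variance_components") <-
    stats::setNames(vc$vcov, vc$grp)
  attr(out, "pruning_path") <- path
  attr(out, "random_retained") <- random
  attr(out, "n") <- stats::nobs(fit)
  attr(out, "descriptor") <- paste(
    "lmm:", paste(deparse(formula), collapse = ""),
    "+", paste(sprintf("(1|%s)", random), collapse = " + ")
  )
  attr(out, "engine") <- "lmer"
  class(out) <- c("model_fit", class(out))
  out
}

#' Heart-rate change model per condition
#'
#' Quantifies the within-exercise decline in heart rate: the outcome is HR
#' change (final minus first sample, bpm) per participant recording, fitted
#' as an intercept-only mixed model with a participant random intercept to
#' account for repeated participation across rounds. With no repeated
#' participation the model reduces to a one-sample t-test on the changes.
#'
#' @param hr_changes A tibble with columns `participant`, `condition` and
#'   `change` (bpm), one row per recording.
#' @return A tibble with one row per condition: `condition`, `estimate`
#'   (mean change, bpm), `se`, `statistic`, `df`, `p_value`, `n`, `engine`.
#' @export
hr_change_model <- function(hr_changes) {
  stopifnot(all(c("participant", "condition", "change") %in%
                  names(hr_changes)))
  rows <- lapply(sort(unique(hr_changes$condition)), function(cc) {
    d <- hr_changes[hr_changes$condition == cc, , drop = FALSE]
    repeated <- any(duplicated(d$participant))
    if (repeated && stats::var(d$change) > 0) {
      f <- tryCatch(
        suppressMessages(suppressWarnings(
          lmerTest::lmer(change ~ 1 + (1 | participant), data = d,
                         REML = TRUE)
        )),
        error = function(e) NULL
      )
    } else {
      f <- NULL
    }
    if (!is.null(f)) {
      cf <- stats::coef(summary(f))
      tibble::tibble(
        condition = cc, estimate = cf[1, "Estimate"], se = cf[1, "Std. Error"],
        statistic = cf[1, "t value"], df = cf[1, "df"],
        p_value = cf[1, "Pr(>|t|)"], n = nrow(d), engine = "lmer"
      )
    } else if (stats::var(d$change) == 0) {
      # degenerate: all changes identical, residual variance 0
      tibble::tibble(
        condition = cc, estimate = mean(d$change), se = 0,
        statistic = NA_real_, df = nrow(d) - 1, p_value = NA_real_,
        n = nrow(d), engine = "degenerate"
      )
    } else {
      tt <- stats::t.test(d$change)
      tibble::tibble(
        condition = cc, estimate = unname(tt$estimate),
        se = stats::sd(d$change) / sqrt(nrow(d)),
        statistic = unname(tt$statistic), df = unname(tt$parameter),
        p_value = tt$p.value, n = nrow(d), engine = "t-test"
      )
    }
  })
  dplyr::bind_rows(rows)
}

#' Extract last-minus-first heart-rate changes from a study bundle
#'
#' @param bundle A `study_bundle`.
#' @return A tibble with `participant`, `round`, `condition`, `change`
#'   (final minus first bpm sample).
#' @export
hr_changes_from_bundle <- function(bundle) {
  roster <- bundle$roster
  rows <- list()
  for (i in seq_len(nrow(roster))) {
    for (m in c("member_a", "member_b")) {
      p <- roster[[m]][i]
      x <- bundle$signals[[signal_key(p, roster$round[i], "hr")]]
      if (is.null(x) || length(x) < 2) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant = p, round = roster$round[i],
        condition = roster$condition[i],
        change = x[length(x)] - x[1]
      )
    }
  }
  dplyr::bind_rows(rows)
}
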