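#' Pipeline configuration with named study profiles
#'
#' Assembles every knob of the end-to-end analysis. The `study1_smile`
#' profile reproduces the smile-synchrony parameter set: 25 Hz signals,
#' integer rounding plus a 4-sample (160 ms) rolling mean, WCLC with a 60-s
#' window (1500 samples), 1-s (25-sample) steps and lags up to +/- 1 s in
#' 1-sample (0.04 s) increments, and pseudo pairs drawn from all
#' never-partnered same-condition participants. The `study2_hr` profile
#' reproduces the heart-rate set: 0.5 Hz signals, AR prewhitening, WCLC with
#' a 60-s window, 2-s (one-sample) steps and +/- 2 s (one-sample) lags,
#' round-matched pseudo pairs, and six Bonferroni-corrected contrasts at
#' alpha 0.05.
#'
#' @param profile `"study1_smile"`, `"study2_hr"` or `"custom"`.
#' @param sim A [sim_config()]; profile defaults are used when `NULL`.
#' @param ... Overrides for individual fields (e.g. `alpha`, `wclc_step_s`,
#'   `max_pseudo_pairs`, `exclude_familiar`, `wclc_max_pairs`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(profile = c("study1_smile", "study2_hr", "custom"),
                            sim = NULL, ...) {
  profile <- match.arg(profile)
  base <- switch(profile,
    study1_smile = list(
      modality = "smile",
      smooth_samples = 4,
      wclc_window_s = 60, wclc_step_s = 1, wclc_max_lag_s = 1,
      wclc_lag_step_samples = 1L,
      scope = "any",
      sim_defaults = list(conditions = c("gazing", "jlm"))
    ),
    study2_hr = list(
      modality = "hr",
      smooth_samples = NA,
      wclc_window_s = 60, wclc_step_s = 2, wclc_max_lag_s = 2,
      wclc_lag_step_samples = 1L,
      scope = "round_matched",
      sim_defaults = list(conditions = c("eyes_closed", "gazing", "jlm"),
                          n_rounds = 6L)
    ),
    custom = list(
      modality = "smile",
      smooth_samples = 4,
      wclc_window_s = 60, wclc_step_s = 1, wclc_max_lag_s = 1,
      wclc_lag_step_samples = 1L,
      scope = "any",
      sim_defaults = list()
    )
  )
  if (is.null(sim)) sim <- do.call(sim_config, base$sim_defaults)
  cfg <- list(
    profile = profile,
    sim = sim,
    modality = base$modality,
    smooth_samples = base$smooth_samples,
    method = "pearson",
    max_ar_order = NULL,
    wclc_window_s = base$wclc_window_s,
    wclc_step_s = base$wclc_step_s,
    wclc_max_lag_s = base$wclc_max_lag_s,
    wclc_lag_step_samples = base$wclc_lag_step_samples,
    wclc_max_pairs = 20L,
    scope = base$scope,
    max_pseudo_pairs = Inf,
    exclude_familiar = FALSE,
    alpha = 0.05,
    seed = sim$seed
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown pipeline_config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full synchrony pipeline
#'
#' Executes the stages simulate (or ingest) -> preprocess -> synchrony ->
#' pseudo-pair null -> inference in order, writing every output table and a
#' manifest (configuration echo and hash, seed, stage counts, exclusions) to
#' `out_dir`. Rerunning with the same configuration reproduces identical
#' numbers.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param bundle Optional pre-built or ingested `study_bundle`; when `NULL`
#'   a synthetic study is simulated from `config$sim`.
#' @return Invisibly, a list with the bundle, the synchrony table, the
#'   contrast tests, the change-score model fits, the WCLC time course and
#'   the manifest.
#' @export
run_pipeline <- function(config, out_dir, bundle = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  bundle <- stage("simulate", {
    if (is.null(bundle)) simulate_study(config$sim) else bundle
  })
  stage("write-data", write_study(bundle, file.path(out_dir, "data")))

  sync <- stage("synchrony", synchrony_table(
    bundle, modality = config$modality, scope = config$scope,
    method = config$method,
    smooth_samples = if (is.na(config$smooth_samples)) 4 else config$smooth_samples,
    max_order = config$max_ar_order,
    max_pseudo_pairs = config$max_pseudo_pairs,
    exclude_familiar = config$exclude_familiar,
    seed = config$seed
  ))
  readr::write_csv(sync, file.path(out_dir, "synchrony.csv"))

  timecourse <- stage("wclc", pipeline_wclc(bundle, config, sync))
  if (!is.null(timecourse)) {
    readr::write_csv(timecourse, file.path(out_dir, "wclc_timecourse.csv"))
  }

  tests <- stage("pair-vs-pseudo", pair_vs_pseudo_tests(sync, alpha = config$alpha))
  readr::write_csv(tests, file.path(out_dir, "pair_vs_pseudo_tests.csv"))

  models <- stage("change-models", change_score_models(bundle, sync))
  readr::write_csv(models, file.path(out_dir, "change_models.csv"))

  hr_fit <- NULL
  if (config$modality == "hr") {
    hr_fit <- stage("hr-change", hr_change_model(hr_changes_from_bundle(bundle)))
    readr::write_csv(hr_fit, file.path(out_dir, "hr_change.csv"))
  }

  rate <- if (config$modality == "smile") config$sim$smile_rate_hz else config$sim$hr_rate_hz
  manifest <- list(
    profile = config$profile,
    seed = config$seed,
    config_hash = content_hash(unclass(config)),
    r_version = as.character(getRversion()),
    modality = config$modality,
    wclc = list(
      window_s = config$wclc_window_s,
      window_samples = round(config$wclc_window_s * rate),
      step_s = config$wclc_step_s,
      max_lag_s = config$wclc_max_lag_s,
      lag_step_samples = config$wclc_lag_step_samples,
      lag_step_s = config$wclc_lag_step_samples / rate
    ),
    scope = attr(sync, "scope"),
    counts = list(
      real_dyads = sum(sync$pair_type == "real"),
      pseudo_pairs = sum(sync$pair_type == "pseudo"),
      eligible = sum(sync$eligible),
      excluded = sum(!sync$eligible),
      skipped_missing_signals = length(attr(sync, "skipped"))
    ),
    exclusions_by_reason = as.list(attr(sync, "exclusions")),
    bonferroni = list(alpha = config$alpha,
                      m = nrow(tests),
                      threshold = unique(tests$threshold))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(bundle = bundle, synchrony = sync, tests = tests,
                 models = models, timecourse = timecourse,
                 hr_change = hr_fit, manifest = manifest))
}

# WCLC on a capped number of real and pseudo pairs, aggregated to the mean
# peak-synchrony time course per condition x pair type.
pipeline_wclc <- function(bundle, config, sync) {
  rate <- if (config$modality == "smile") config$sim$smile_rate_hz else config$sim$hr_rate_hz
  n_samples <- round(config$sim$duration_s * rate)
  if (round(config$wclc_window_s * rate) > n_samples) return(NULL)

  fetch <- function(p, r) {
    x <- bundle$signals[[signal_key(p, r, config$modality)]]
    if (is.null(x)) return(NULL)
    if (config$modality == "smile") {
      prep_smile(x, if (is.na(config$smooth_samples)) 4 else config$smooth_samples)
    } else if (stats::var(x) > 0) {
      pw <- prewhiten_ar(x, config$max_ar_order)
      # pad front so prewhitened series stay window-aligned across pairs
      c(rep(NA_real_, pw$start_index - 1L), pw$residuals)
    } else {
      x - mean(x)
    }
  }

  eligible <- sync[sync$eligible, , drop = FALSE]
  picks <- eligible |>
    dplyr::group_by(.data$condition, .data$pair_type) |>
    dplyr::slice_head(n = config$wclc_max_pairs) |>
    dplyr::ungroup()
  if (nrow(picks) == 0) return(NULL)

  lookup <- pair_members(bundle$roster, picks$pair_id)
  rows <- list()
  for (i in seq_len(nrow(picks))) {
    mem <- lookup[[picks$pair_id[i]]]
    a <- fetch(mem$member_a, mem$round_a)
    b <- fetch(mem$member_b, mem$round_b)
    if (is.null(a) || is.null(b)) next
    if (config$modality == "hr") {
      # drop leading NAs jointly so both series share a grid
      start <- max(which(!is.na(a))[1], which(!is.na(b))[1])
      a <- a[start:length(a)]
      b <- b[start:length(b)]
      if (round(config$wclc_window_s * rate) > length(a)) next
    }
    w <- wclc(a, b, rate_hz = rate, window_s = config$wclc_window_s,
              step_s = config$wclc_step_s, max_lag_s = config$wclc_max_lag_s,
              lag_step_samples = config$wclc_lag_step_samples,
              method = config$method)
    w$pair_id <- picks$pair_id[i]
    w$condition <- picks$condition[i]
    w$pair_type <- picks$pair_type[i]
    rows[[length(rows) + 1L]] <- w
  }
  if (!length(rows)) return(NULL)
  all_w <- dplyr::bind_rows(rows)
  # HR prewhitening shifts the first usable window per pair; aggregate on
  # the intersection grid
  common <- Reduce(intersect, lapply(rows, function(w) w$window_start_s))
  peak_timecourse(all_w[all_w$window_start_s %in% common, , drop = FALSE])
}

# Resolve the member recordings behind each pair id (real dyads from the
# roster; pseudo ids encode members and rounds).
pair_members <- function(roster, pair_ids) {
  out <- list()
  for (pid in unique(pair_ids)) {
    i <- match(pid, roster$dyad_id)
    if (!is.na(i)) {
      out[[pid]] <- list(member_a = roster$member_a[i], round_a = roster$round[i],
                         member_b = roster$member_b[i], round_b = roster$round[i])
    } else {
      m <- regmatches(pid, regexec(
        "^pseudo_.+_(s\\d+_p\\d+)_r(\\d+)_(s\\d+_p\\d+)_r(\\d+)$", pid))[[1]]
      if (length(m) != 5) stop("cannot resolve pair id: ", pid)
      out[[pid]] <- list(member_a = m[2], round_a = as.integer(m[3]),
                         member_b = m[4], round_b = as.integer(m[5]))
    }
  }
  out
}

# Dyad-level change-score regressions: for each pre/post measure, the dyad's
# mean change regressed on synchrony, mean signal level, condition and their
# interactions (reduced automatically when only one condition is present),
# fitted separately for real and pseudo pairs, on z-scored variables.
change_score_models <- function(bundle, sync) {
  ratings <- bundle$ratings
  measures <- unique(ratings$measure[!is.na(ratings$pre)])
  measures <- c(measures, intersect("dictator_keep", unique(ratings$measure)))
  for (msr in measures) ratings <- standardize(ratings, msr)
  changes <- dyad_change_scores(ratings)

  real <- sync[sync$pair_type == "real" & sync$eligible, , drop = FALSE]
  if (nrow(real) < 4) return(empty_model_table())
  real$z_r <- as.numeric(scale(real$r))
  real$z_mean <- as.numeric(scale(real$mean_pair))

  rows <- list()
  for (msr in measures) {
    d <- dplyr::inner_join(
      changes[changes$measure == msr, ],
      real[, c("pair_id", "z_r", "z_mean")],
      by = c("dyad_id" = "pair_id")
    )
    if (nrow(d) < 5) next
    multi_cond <- length(unique(d$condition)) > 1
    form <- if (multi_cond) {
      change ~ z_r * condition + z_mean * condition
    } else {
      change ~ z_r + z_mean
    }
    fit <- tryCatch(fit_ols(form, d), error = function(e) NULL)
    if (is.null(fit)) next
    fit$measure <- msr
    rows[[length(rows) + 1L]] <- fit
  }
  if (!length(rows)) return(empty_model_table())
  dplyr::bind_rows(lapply(rows, function(f) {
    tibble::as_tibble(f)[, c("measure", "term", "estimate", "se",
                             "statistic", "df", "p_value")]
  }))
}

empty_model_table <- function() {
  tibble::tibble(measure = character(), term = character(),
                 estimate = numeric(), se = numeric(), statistic = numeric(),
                 df = numeric(), p_value = numeric())
}
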