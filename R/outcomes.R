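#' Measure definitions for the ratings instrument
#'
#' Ranges of the self-report and behavioural measures: closeness on the
#' 7-point pictorial overlapping-circles scale, the slider measures on
#' 0--100, the dictator-game allocation of a fixed stake on 0--100, and the
#' post-exercise emotion sliders on 0--100.
#'
#' @return A tibble with columns `measure`, `lo`, `hi`, `integer`
#'   (integer-valued scale), `has_pre` (assessed before and after the
#'   exercise) and `pre_mean`, `pre_sd` (generator baselines).
#' @export
measure_ranges <- function() {
  tibble::tribble(
    ~measure,         ~lo, ~hi, ~integer, ~has_pre, ~pre_mean, ~pre_sd,
    "closeness",        1,   7,  TRUE,     TRUE,        2.5,      1.2,
    "warmth",           0, 100,  FALSE,    TRUE,       55,       15,
    "competence",       0, 100,  FALSE,    TRUE,       55,       15,
    "attractiveness",   0, 100,  FALSE,    TRUE,       50,       15,
    "friendship",       0, 100,  FALSE,    TRUE,       50,       15,
    "attraction",       0, 100,  FALSE,    TRUE,       40,       15,
    "dictator_keep",    0, 100,  FALSE,    FALSE,      50,       15,
    "anxious",          0, 100,  FALSE,    FALSE,      30,       20,
    "relaxed",          0, 100,  FALSE,    FALSE,      55,       20,
    "comfortable",      0, 100,  FALSE,    FALSE,      55,       20,
    "happy",            0, 100,  FALSE,    FALSE,      55,       20
  )
}

#' Simulate pre/post ratings and dictator-game allocations
#'
#' For every rater x round x measure, a pre-exercise value is drawn around
#' the measure's baseline; the post-exercise value is
#' `pre + condition_effect + gamma * (coupling - mean(coupling)) + noise`,
#' clipped to the measure's range (and rounded for the 7-point closeness
#' scale), where `coupling` is the dyad's latent coupling from `truth` and
#' `gamma = cfg$outcome_effect`. Post-only measures (dictator allocation,
#' emotions) receive the same additive structure on their single value.
#' Clipping rather than resampling keeps the effect structure monotone in
#' coupling.
#'
#' @param roster A roster tibble from [make_roster()].
#' @param truth A tibble with columns `dyad_id` and `coupling` (the latent
#'   coupling driving outcome change; one row per real dyad).
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#'
#' @return A long tibble of ratings: `rater_id`, `partner_id`, `dyad_id`,
#'   `round`, `condition`, `measure`, `pre` (NA for post-only measures),
#'   `post`, `familiarity`.
#' @export
simulate_outcomes <- function(roster, truth, cfg, seed = cfg$seed) {
  stopifnot(all(c("dyad_id", "coupling") %in% names(truth)))
  missing_truth <- setdiff(roster$dyad_id, truth$dyad_id)
  if (length(missing_truth)) {
    stop("truth lacks coupling values for dyads: ",
         paste(utils::head(missing_truth, 5), collapse = ", "))
  }
  cbar <- mean(truth$coupling)
  cmap <- stats::setNames(truth$coupling, truth$dyad_id)
  mr <- measure_ranges()

  # two raters per dyad row: each member rates the other
  raters <- tibble::tibble(
    rater_id = c(roster$member_a, roster$member_b),
    partner_id = c(roster$member_b, roster$member_a),
    dyad_id = rep(roster$dyad_id, 2),
    round = rep(roster$round, 2),
    condition = rep(roster$condition, 2),
    familiarity = c(roster$familiar_a, roster$familiar_b)
  )

  grid <- tidyr::crossing(raters, mr["measure"])
  grid <- dplyr::left_join(grid, mr, by = "measure")
  grid$coupling <- unname(cmap[grid$dyad_id])
  grid$cond_eff <- vapply(grid$condition, function(cc) condition_effect(cfg, cc),
                          numeric(1))

  with_substream(seed, "outcomes", {
    m <- nrow(grid)
    pre <- stats::rnorm(m, grid$pre_mean, grid$pre_sd)
    pre <- clip(pre, grid$lo, grid$hi)
    pre <- ifelse(grid$integer, round_half_away(pre), pre)
    delta <- grid$cond_eff +
      cfg$outcome_effect * (grid$coupling - cbar) +
      stats::rnorm(m, 0, cfg$outcome_noise_sd)
    post <- clip(pre + delta, grid$lo, grid$hi)
    post <- ifelse(grid$integer, round_half_away(post), post)
    grid$pre <- ifelse(grid$has_pre, pre, NA_real_)
    grid$post <- post
  })

  grid[, c("rater_id", "partner_id", "dyad_id", "round", "condition",
           "measure", "pre", "post", "familiarity")]
}
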