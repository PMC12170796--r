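#' Simulation configuration for a synthetic dyadic meditation study
#'
#' Bundles every parameter of the synthetic-study generator: the pairing
#' design (participants, rounds, conditions), the signal models (bursty
#' bounded smile intensity with probabilistic mimicry; heart rate with an
#' initial arousal decay and optionally coupled AR(1) fluctuations), and the
#' outcome model (pre/post ratings whose change depends linearly on the
#' dyad's latent coupling).
#'
#' Signal defaults mirror the recording setup the analysis assumes: smile
#' intensity on a 0--100 scale sampled at 25 Hz and heart rate in beats per
#' minute sampled at 0.5 Hz, both over 120 s exercises.
#'
#' @param n_participants Number of participants per session (one session per
#'   condition). Must be at least 2.
#' @param n_rounds Number of pairing rounds per session.
#' @param conditions Character vector of condition labels; each condition is
#'   run as its own session with its own participants.
#' @param smile_rate_hz Smile sampling rate in Hz.
#' @param hr_rate_hz Heart-rate sampling rate in Hz.
#' @param duration_s Exercise duration in seconds. `duration_s * rate` must
#'   be a whole number of samples for both modalities.
#' @param smile_burst_rate Spontaneous smile bursts per minute per person.
#' @param smile_burst_amp Peak burst intensity on the 0--100 scale.
#' @param smile_burst_width_s Full width of one half-cosine burst, seconds.
#' @param mimicry_prob Mean probability that a partner's burst elicits a
#'   response burst (per-dyad latent couplings are drawn around this mean).
#' @param mimicry_lag_s Length-2 numeric, lower/upper bound of the uniform
#'   response-lag distribution in seconds.
#' @param nonsmiler_prob Probability that a participant emits an all-zero
#'   smile series in a given round.
#' @param hr_baseline_bpm Resting heart-rate level, bpm.
#' @param hr_arousal_amp_bpm Initial arousal elevation above baseline, bpm;
#'   decays exponentially.
#' @param hr_decay_tau_s Time constant of the arousal decay, seconds.
#' @param hr_ar_coef AR(1) coefficient of the heart-rate fluctuations
#'   (per sample); must satisfy `|hr_ar_coef| < 1`.
#' @param hr_noise_sd Innovation standard deviation of the AR(1)
#'   fluctuations, bpm.
#' @param hr_coupling Mean shared-innovation weight in `[0, 1]`; 0 gives
#'   independent members, 1 gives identical AR fluctuations.
#' @param outcome_effect Slope (`gamma`) of the post-minus-pre change on the
#'   dyad's centred latent coupling, in units of each outcome measure.
#' @param outcome_noise_sd Standard deviation of the outcome change noise,
#'   in measure units.
#' @param condition_effects Named numeric vector of additive post-pre shifts
#'   per condition (measure units); missing conditions default to 0.
#' @param familiarity_prob Probability that a participant reports prior
#'   familiarity with a given partner (ordinal level drawn 1--4), used by the
#'   familiarity-exclusion robustness filter.
#' @param allow_repeats Allow repeated pairings when `n_rounds` exceeds the
#'   number of distinct partners.
#' @param seed Integer RNG seed; all randomness is derived from it through
#'   per-dyad substreams.
#'
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 6, n_rounds = 2, seed = 1)
#' cfg$smile_rate_hz
sim_config <- function(n_participants = 10,
                       n_rounds = 3,
                       conditions = c("gazing", "jlm"),
                       smile_rate_hz = 25,
                       hr_rate_hz = 0.5,
                       duration_s = 120,
                       smile_burst_rate = 3,
                       smile_burst_amp = 70,
                       smile_burst_width_s = 4,
                       mimicry_prob = 0.5,
                       mimicry_lag_s = c(0.2, 1.0),
                       nonsmiler_prob = 0.2,
                       hr_baseline_bpm = 77,
                       hr_arousal_amp_bpm = 12,
                       hr_decay_tau_s = 30,
                       hr_ar_coef = 0.8,
                       hr_noise_sd = 1,
                       hr_coupling = 0.5,
                       outcome_effect = 0.5,
                       outcome_noise_sd = 1,
                       condition_effects = NULL,
                       familiarity_prob = 0.05,
                       allow_repeats = FALSE,
                       seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_rounds = as.integer(n_rounds),
    conditions = as.character(conditions),
    smile_rate_hz = smile_rate_hz,
    hr_rate_hz = hr_rate_hz,
    duration_s = duration_s,
    smile_burst_rate = smile_burst_rate,
    smile_burst_amp = smile_burst_amp,
    smile_burst_width_s = smile_burst_width_s,
    mimicry_prob = mimicry_prob,
    mimicry_lag_s = as.numeric(mimicry_lag_s),
    nonsmiler_prob = nonsmiler_prob,
    hr_baseline_bpm = hr_baseline_bpm,
    hr_arousal_amp_bpm = hr_arousal_amp_bpm,
    hr_decay_tau_s = hr_decay_tau_s,
    hr_ar_coef = hr_ar_coef,
    hr_noise_sd = hr_noise_sd,
    hr_coupling = hr_coupling,
    outcome_effect = outcome_effect,
    outcome_noise_sd = outcome_noise_sd,
    condition_effects = condition_effects,
    familiarity_prob = familiarity_prob,
    allow_repeats = isTRUE(allow_repeats),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  probs <- c(
    mimicry_prob = cfg$mimicry_prob,
    nonsmiler_prob = cfg$nonsmiler_prob,
    hr_coupling = cfg$hr_coupling,
    familiarity_prob = cfg$familiarity_prob
  )
  if (any(probs < 0 | probs > 1)) {
    bad <- names(probs)[probs < 0 | probs > 1]
    stop("probabilities must lie in [0, 1]: ", paste(bad, collapse = ", "))
  }
  pos <- c(
    smile_rate_hz = cfg$smile_rate_hz, hr_rate_hz = cfg$hr_rate_hz,
    duration_s = cfg$duration_s, smile_burst_width_s = cfg$smile_burst_width_s,
    hr_decay_tau_s = cfg$hr_decay_tau_s
  )
  if (any(pos <= 0)) {
    stop("rates, durations and widths must be > 0: ",
         paste(names(pos)[pos <= 0], collapse = ", "))
  }
  if (cfg$smile_burst_rate < 0 || cfg$smile_burst_amp < 0 ||
      cfg$hr_noise_sd < 0 || cfg$outcome_noise_sd < 0) {
    stop("rates, amplitudes and noise SDs must be non-negative")
  }
  if (cfg$n_participants < 2) stop("n_participants must be at least 2")
  if (cfg$n_rounds < 1) stop("n_rounds must be at least 1")
  if (abs(cfg$hr_ar_coef) >= 1) {
    stop("hr_ar_coef implies a non-stationary AR process (|coef| >= 1)")
  }
  for (r in c(cfg$smile_rate_hz, cfg$hr_rate_hz)) {
    n <- cfg$duration_s * r
    if (abs(n - round(n)) > 1e-8) {
      stop("duration_s * rate must give an integer sample count (got ",
           n, ")")
    }
  }
  if (length(cfg$mimicry_lag_s) != 2 || diff(cfg$mimicry_lag_s) < 0 ||
      any(cfg$mimicry_lag_s < 0)) {
    stop("mimicry_lag_s must be an increasing non-negative pair of bounds")
  }
  if (!is.null(cfg$condition_effects) &&
      is.null(names(cfg$condition_effects))) {
    stop("condition_effects must be a named numeric vector")
  }
  cfg
}

# Additive condition shift for one condition label (0 when unspecified).
condition_effect <- function(cfg, condition) {
  ce <- cfg$condition_effects
  if (is.null(ce) || !condition %in% names(ce)) return(0)
  unname(ce[[condition]])
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  design : %d participants x %d rounds, conditions: %s\n",
              x$n_participants, x$n_rounds,
              paste(x$conditions, collapse = ", ")))
  cat(sprintf("  smile  : %g Hz, %g bursts/min, amp %g, width %g s, mimicry %g\n",
              x$smile_rate_hz, x$smile_burst_rate, x$smile_burst_amp,
              x$smile_burst_width_s, x$mimicry_prob))
  cat(sprintf("  hr     : %g Hz, baseline %g bpm + %g bpm decay (tau %g s), AR %g, coupling %g\n",
              x$hr_rate_hz, x$hr_baseline_bpm, x$hr_arousal_amp_bpm,
              x$hr_decay_tau_s, x$hr_ar_coef, x$hr_coupling))
  cat(sprintf("  outcome: gamma %g, noise sd %g\n",
              x$outcome_effect, x$outcome_noise_sd))
  cat(sprintf("  seed   : %d\n", x$seed))
  invisible(x)
}
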