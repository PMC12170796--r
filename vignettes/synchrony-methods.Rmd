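---
title: "Methods: synchrony estimation with a pseudo-pair null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synchrony estimation with a pseudo-pair null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

This vignette documents the statistical methods in `dyadsync`: what is being
estimated, how the synthetic study generator is constructed, why each
preprocessing step exists, and where the approach is known to be limited.

## The estimation problem

In partner-based interaction experiments, pairs of strangers complete short
exercises (for example mutual gazing, a guided loving-kindness meditation,
or an eyes-closed control) while two signals are recorded per person: smile
intensity on a 0--100 scale at 25 Hz, and heart rate in bpm at 0.5 Hz.
Participants also rate outcomes such as interpersonal closeness before and
after each exercise.

Two inferential targets follow:

1. **Synchrony above chance.** Are partners' signals more correlated than
   those of people who did the same exercise but never met? "More correlated
   than zero" is the wrong bar, because shared task structure alone
   (everyone smiles at the instructions; everyone's heart rate declines
   from initial arousal) induces correlation between strangers.
2. **Synchrony as a predictor.** Does a dyad's synchrony predict its change
   in rated closeness and related outcomes?

## Synchrony estimators

### Global synchrony

`global_synchrony()` is the Pearson (optionally Spearman) correlation of
the two members' full preprocessed series. It is cheap, has a
well-understood null distribution after prewhitening, and is the quantity
entering the pseudo-pair contrasts.

### Windowed cross-lagged correlation (WCLC)

`wclc()` resolves synchrony in time and lag. A window of `window_s` seconds
(default 60) slides in steps of `step_s`; within each window, the
correlation is computed for every lag on a symmetric grid up to
`max_lag_s`, in increments of `lag_step_samples`. The per-window **peak
synchrony** is the maximum correlation over the lag grid, with its argmax
lag; a positive lag means member B follows member A. Conventions worth
stating explicitly:

- Ties are broken toward the smallest absolute lag, and negative before
  positive at equal magnitude, so the estimator does not manufacture
  spurious lead--lag asymmetry.
- Windows in which every lag yields a negative correlation are *flagged*
  (`all_negative`) rather than dropped: anti-phase behaviour is data.
- Window and step lengths must be whole numbers of samples; the function
  refuses fractional-sample grids rather than rounding silently.

Peak-picking over a lag grid is a maximum of correlated noisy variables, so
even independent series have positively biased peak values. This bias is a
property of the estimator, not a bug, and it is why all inference runs
against the pseudo-pair null computed with the *same* estimator. The test
suite bounds the bias directly (100 independent 25 Hz pairs on the default
grid keep the mean peak time course within ±0.05).

`peak_timecourse()` averages the per-window peaks across pairs within
condition and pair type, with a normal-approximation 95% half-width, and
refuses to aggregate pairs computed on different window grids.

### Preprocessing

**Smile.** Raw intensities are rounded half-away-from-zero to integers
(`round_to_integers()`), mimicking the quantization of expression-coding
software, then smoothed with a centered 4-sample (160 ms) rolling mean
(`smooth_rolling_mean()`; even windows take one extra sample to the right,
edges shrink the window rather than dropping samples). `prep_smile()`
bundles both. Pairs in which a member never smiled at all are excluded by
`smile_eligibility()` with the reason recorded — a flat series has no
defined correlation, and imputing one would bias the null.

**Heart rate.** `prewhiten_ar()` fits an AR model by Yule--Walker with AIC
order selection (maximum order `floor(10 * log10(n))`) and returns the
residuals, which start at sample `order + 1`; pair alignment trims the
longer residual series at the front. Prewhitening exists because both
members share an exponential arousal decay: over a 120-s recording this
shared trend alone drives the raw inter-partner correlation above 0.8 in
simulation, while the correlation of the prewhitened residuals of uncoupled
members falls below 0.1. (That check is run at 2 Hz so the null correlation
floor, about `sqrt(2/pi)/sqrt(n)`, sits safely under 0.1; at 0.5 Hz a 120-s
recording has only 60 samples and the floor alone is ≈ 0.10.)

## The pseudo-pair null

`enumerate_pseudo_pairs()` builds the surrogate population:

- scope `"any"`: every pair of same-condition participants who were never
  actually partnered, crossed over all combinations of their per-round
  recordings. Suited to signals without strong within-session time
  structure (smiles).
- scope `"round_matched"`: within each round, participants recorded in that
  round but not paired with each other. Suited to heart rate, where the
  arousal trajectory depends on elapsed session time, so surrogates must be
  matched on round.

`synchrony_table()` computes one record per real dyad and per pseudo
pairing with identical preprocessing, optional familiarity exclusion, and a
seeded cap on the pseudo enumeration when it grows combinatorially large.
`pair_vs_pseudo_tests()` then runs pooled-variance t-tests (Welch by flag)
for real-versus-pseudo within each condition and all between-condition
comparisons among real pairs, with per-test threshold `alpha / m`; three
conditions give the standard six-contrast family and threshold
0.05/6 ≈ 0.008.

## Outcome models

`standardize()` scales each pre/post measure by its pre-exercise mean and
SD (pooled across conditions by default), so changes read in pre-SD units;
post-only measures are z-scored. `dyad_change_scores()` averages post-minus-
pre over the two members. The dyad-level regressions (`fit_ols()`, closed
form via QR with classical SEs) relate change to synchrony, mean signal
level, condition and interactions. For rater-level models with repeated
participation, `fit_dyadic_mixed()` fits random intercepts for participant,
dyad, partner and round by REML, and prunes the smallest-variance component
whenever the fit is singular, collapsing to OLS only when no random
intercept survives; the pruning path is recorded in the result rather than
decided silently. `hr_change_model()` fits the within-exercise heart-rate
change (last minus first sample) per condition with a participant random
intercept, reducing to a one-sample t-test without repeated participation.

## The synthetic study generator

All validation rests on `simulate_study()`, which generates a full study
from a single seed through per-dyad substreams (so any dyad is reproducible
in isolation and results do not depend on simulation order).

**Roster.** `make_roster()` uses the circle-method round robin: within one
session per condition, every participant meets a new partner each round,
with one person sitting out per round when the count is odd. Repeat
pairings are impossible by construction unless explicitly allowed.

**Smile model.** Each member emits spontaneous bursts as a Poisson process
(default 3 bursts/min), rendered as half-cosine bumps (default width 4 s,
peak amplitude 70 with uniform 0.5--1 scaling, clipped to 0--100). Mimicry
is probabilistic: each spontaneous burst of one member elicits a partner
response with probability equal to the dyad's latent coupling, after a
uniform 0.2--1.0 s lag; responses do not themselves cascade. With
probability `nonsmiler_prob` (default 0.2) a member produces an all-zero
series — non-smiling participants are common enough in practice that the
eligibility filter needs realistic exercise.

**Heart-rate model.** `hr = baseline + amp * exp(-t / tau) + AR(1)`, with
defaults baseline 77 bpm, arousal amplitude 12 bpm, decay constant 30 s, AR
coefficient 0.8 per sample and innovation SD 1. Coupling enters through
shared innovations: `e_i = sqrt(1 - c) * u_i + sqrt(c) * s`, so `c = 0`
gives independent members and `c = 1` identical fluctuations around the
shared trend.

**Latent couplings and outcomes.** Per-dyad couplings are drawn from a Beta
distribution with the configured mean and concentration 5, so ground truth
varies across dyads while matching the configured average (degenerate at
mean 0 or 1). Outcome change is additive:
`post - pre = condition effect + gamma * (coupling - mean coupling) + noise`,
clipped to each measure's range and rounded to the instrument's resolution
(the closeness scale stays on integers 1--7). This is deliberately the
simplest model under which the downstream estimators should succeed; it is
a validation harness, not a cognitive theory.

**Problem-size defaults** (10 participants per session, 3 rounds, 120-s
recordings) keep a full simulated study around a second while leaving every
estimator's sampling error small enough for the Monte-Carlo checks in the
test suite.

## Validation summary

`tests/testthat/test-acceptance.R` (one test per criterion) and
`scripts/acceptance.R` recompute, from scratch: the six-contrast Bonferroni
threshold (0.008); the smile-profile WCLC grid (1500-sample windows,
0.04-s lag steps); exact agreement of `wclc()` with an exhaustive
double-loop oracle; null calibration (mean synchrony of uncoupled pairs
within ±0.02 of zero; t-test rejection rate within [0.03, 0.07] at α =
0.05); strict monotonicity of mean synchrony in the true coupling;
trend-confound removal by prewhitening; recovery of the outcome slope γ ∈
{0, 0.25, 0.5} within ±0.1 with 90--98% CI coverage over 200 replicates;
pseudo-pair counting identities; and the closed-form expected heart-rate
change `amp * (exp(-120/tau) - 1) ≈ -9.82` bpm.

## Limitations

- The generator's mimicry is event-triggered and unidirectional per burst;
  it does not model sustained mutual facial regulation, and smile coupling
  is not identified separately from burst rate at very low activity.
- Prewhitening assumes an adequately low-order AR structure; strongly
  nonstationary heart rate (e.g. movement artifacts) violates it, and at
  0.5 Hz the short recordings leave wide null variability for any
  correlation-based estimator.
- The pseudo-pair null controls for condition and (in round-matched scope)
  elapsed time, but not for unmodelled covariates such as sex composition
  or time of day.
- Mixed-model pruning by smallest estimated variance is a heuristic; with
  few clusters, variance components near zero are weakly identified, and
  the recorded pruning path should be inspected rather than trusted
  blindly.
- The outcome model is linear with homoscedastic noise; ceiling effects on
  bounded scales are handled only by clipping, which slightly attenuates
  recovered slopes at extreme parameter settings.
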