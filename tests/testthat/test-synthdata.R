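test_that("round-robin roster pairs everyone exactly once on 4 participants", {
  r <- make_roster(4, 3, "gazing", seed = 1)
  expect_equal(nrow(r), 6)
  keys <- paste(pmin(r$member_a, r$member_b), pmax(r$member_a, r$member_b))
  expect_equal(sort(keys), sort(combn(sprintf("s1_p%02d", 1:4), 2,
                                      paste, collapse = " ")))
  # no self-pairing, 2 dyads per round
  expect_true(all(r$member_a != r$member_b))
  expect_equal(as.integer(table(r$round)), rep(2L, 3))
})

test_that("odd participant counts leave one person out per round", {
  r <- make_roster(5, 1, "gazing", seed = 2)
  expect_equal(nrow(r), 2)
  out <- attr(r, "sat_out")
  expect_equal(nrow(out), 1)
  expect_false(out$participant %in% c(r$member_a, r$member_b))
})

test_that("larger rosters contain no repeated pairing (brute-force scan)", {
  for (seed in 1:3) {
    r <- make_roster(10, 4, "gazing", seed = seed)
    expect_equal(nrow(r), 20)
    keys <- paste(pmin(r$member_a, r$member_b), pmax(r$member_a, r$member_b))
    expect_equal(anyDuplicated(keys), 0L)
  }
})

test_that("infeasible round counts error unless repeats are allowed", {
  expect_error(make_roster(4, 4, "gazing"), "allow_repeats")
  r <- make_roster(4, 4, "gazing", allow_repeats = TRUE)
  expect_equal(nrow(r), 8)
})

test_that("conditions map to disjoint sessions with one label per dyad", {
  r <- make_roster(6, 2, c("eyes_closed", "gazing", "jlm"), seed = 3)
  expect_equal(sort(unique(r$condition)), c("eyes_closed", "gazing", "jlm"))
  by_cond <- split(c(r$member_a, r$member_b), rep(r$condition, 2))
  people <- lapply(by_cond, unique)
  expect_equal(length(Reduce(intersect, people)), 0)
  expect_true(all(table(r$dyad_id) == 1))
})

test_that("universal non-smilers produce all-zero smile series", {
  cfg <- tiny_cfg(nonsmiler_prob = 1)
  s <- simulate_smile_dyad(cfg, coupling = 0, seed = 1)
  expect_true(all(s$a == 0) && all(s$b == 0))
})

test_that("full mimicry makes every spontaneous burst answered within the lag window", {
  cfg <- tiny_cfg(nonsmiler_prob = 0, smile_burst_rate = 6, duration_s = 120)
  for (seed in 1:5) {
    s <- simulate_smile_dyad(cfg, coupling = 1, seed = seed)
    # event matching: each spontaneous burst is answered by a partner event
    # 0.2-1.0 s later (responses themselves do not cascade)
    answered <- function(spont, partner_events) {
      vapply(spont, function(t0) {
        any(partner_events >= t0 + 0.2 - 1e-9 &
              partner_events <= t0 + 1.0 + 1e-9)
      }, logical(1))
    }
    expect_true(all(answered(attr(s, "spont_a"), attr(s, "events_b"))))
    expect_true(all(answered(attr(s, "spont_b"), attr(s, "events_a"))))
    expect_true(all(s$a >= 0 & s$a <= 100))
    expect_true(all(s$b >= 0 & s$b <= 100))
  }
})

test_that("smile series lengths and determinism follow the config", {
  cfg <- tiny_cfg()
  s1 <- simulate_smile_dyad(cfg, 0.5, seed = 9)
  s2 <- simulate_smile_dyad(cfg, 0.5, seed = 9)
  expect_identical(s1, s2)
  expect_length(s1$a, cfg$duration_s * cfg$smile_rate_hz)
})

test_that("noise-free uncoupled heart rate is constant at baseline", {
  cfg <- tiny_cfg(hr_arousal_amp_bpm = 0, hr_noise_sd = 0)
  h <- simulate_hr_dyad(cfg, coupling = 0, seed = 1)
  expect_equal(h$a, rep(cfg$hr_baseline_bpm, length(h$a)))
  expect_equal(h$b, rep(cfg$hr_baseline_bpm, length(h$b)))
})

test_that("non-stationary AR coefficients are rejected", {
  expect_error(sim_config(hr_ar_coef = 1), "non-stationary")
  cfg <- tiny_cfg()
  cfg$hr_ar_coef <- 1.2
  expect_error(simulate_hr_dyad(cfg, 0, seed = 1), "non-stationary")
})

test_that("fully coupled members have near-identical prewhitened residuals", {
  cfg <- sim_config(duration_s = 120)
  rs <- vapply(1:20, function(seed) {
    h <- simulate_hr_dyad(cfg, coupling = 1, seed = seed)
    pa <- prewhiten_ar(h$a)
    pb <- prewhiten_ar(h$b)
    start <- max(pa$start_index, pb$start_index)
    a <- pa$residuals[(start - pa$start_index + 1):length(pa$residuals)]
    b <- pb$residuals[(start - pb$start_index + 1):length(pb$residuals)]
    cor(a, b)
  }, numeric(1))
  # shared innovations imply identical residuals up to initialisation and
  # per-member AR order selection
  expect_gt(mean(rs), 0.95)
})

test_that("ensemble mean heart rate recovers the arousal decay", {
  cfg <- sim_config(hr_arousal_amp_bpm = 10, hr_decay_tau_s = 30)
  n <- round(cfg$duration_s * cfg$hr_rate_hz)
  acc <- numeric(n)
  n_dyads <- 200
  for (seed in seq_len(n_dyads)) {
    h <- simulate_hr_dyad(cfg, coupling = 0, seed = seed)
    acc <- acc + h$a + h$b
  }
  m <- acc / (2 * n_dyads)
  t <- (seq_len(n) - 1) / cfg$hr_rate_hz
  fit <- nls(m ~ b0 + amp * exp(-t / tau),
             start = list(b0 = 70, amp = 5, tau = 20))
  est <- coef(fit)
  expect_lt(abs(est[["amp"]] - 10) / 10, 0.2)
  expect_lt(abs(est[["b0"]] - cfg$hr_baseline_bpm), 1)
})

test_that("outcomes are unchanged when all effects and noise are zero", {
  cfg <- tiny_cfg(outcome_effect = 0, outcome_noise_sd = 0)
  roster <- make_roster(4, 1, "gazing", seed = 1)
  truth <- tibble::tibble(dyad_id = roster$dyad_id, coupling = c(0.2, 0.8))
  out <- simulate_outcomes(roster, truth, cfg, seed = 1)
  has_pre <- !is.na(out$pre)
  expect_equal(out$post[has_pre], out$pre[has_pre])
})

test_that("ratings respect measure ranges, closeness stays on the 7-point scale", {
  cfg <- tiny_cfg(outcome_effect = 10, outcome_noise_sd = 30,
                  condition_effects = c(gazing = 20))
  roster <- make_roster(6, 2, "gazing", seed = 4)
  truth <- tibble::tibble(dyad_id = roster$dyad_id,
                          coupling = runif(nrow(roster)))
  out <- simulate_outcomes(roster, truth, cfg, seed = 2)
  mr <- measure_ranges()
  for (i in seq_len(nrow(mr))) {
    v <- out[out$measure == mr$measure[i], ]
    expect_true(all(v$post >= mr$lo[i] & v$post <= mr$hi[i]))
  }
  ios <- out$post[out$measure == "closeness"]
  expect_true(all(ios %in% 1:7))
})

test_that("simulate_study is deterministic and structurally complete", {
  cfg <- sim_config(n_participants = 6, n_rounds = 2,
                    conditions = c("gazing", "jlm"), duration_s = 40,
                    seed = 11)
  b1 <- simulate_study(cfg)
  b2 <- simulate_study(cfg)
  expect_identical(b1[c("roster", "signals", "ratings", "truth")],
                   b2[c("roster", "signals", "ratings", "truth")])
  # every real dyad has both members' signals in both modalities
  for (i in seq_len(nrow(b1$roster))) {
    for (m in c("member_a", "member_b")) {
      for (mod in c("smile", "hr")) {
        key <- paste(b1$roster[[m]][i], b1$roster$round[i], mod, sep = "|")
        expect_false(is.null(b1$signals[[key]]))
      }
    }
  }
  expect_setequal(b1$truth$dyad_id, b1$roster$dyad_id)
})

test_that("uncoupled simulations yield independent members on average", {
  cfg <- tiny_cfg(nonsmiler_prob = 0, duration_s = 120)
  rs <- vapply(1:80, function(seed) {
    s <- simulate_smile_dyad(cfg, coupling = 0, seed = seed)
    r <- lagged_correlation(prep_smile(s$a), prep_smile(s$b))
    if (is.na(r)) 0 else r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})
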