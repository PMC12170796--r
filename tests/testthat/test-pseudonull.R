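test_that("a complete round robin leaves no never-partnered pairs", {
  r <- make_roster(4, 3, "gazing", seed = 1) # everyone met everyone
  expect_equal(nrow(enumerate_pseudo_pairs(r, "gazing", "any")), 0)
})

test_that("round-matched pseudo pairs are the non-partner combinations per round", {
  r <- make_roster(6, 1, "gazing", seed = 2)
  ep <- enumerate_pseudo_pairs(r, "gazing", "round_matched")
  expect_equal(nrow(ep), choose(6, 2) - 3) # 12
  expect_true(all(ep$round_a == 1 & ep$round_b == 1))
})

test_that("pseudo enumeration matches a brute-force set-difference oracle", {
  for (seed in 1:3) {
    r <- make_roster(8, 3, "gazing", seed = seed)
    real <- paste(pmin(r$member_a, r$member_b),
                  pmax(r$member_a, r$member_b))
    people <- sort(unique(c(r$member_a, r$member_b)))
    never <- combn(people, 2, paste, collapse = " ")
    never <- setdiff(never, real)
    # "any" scope: each never-partnered pair contributes rounds_a x rounds_b
    # recording combinations; here everyone attends all 3 rounds
    ep <- enumerate_pseudo_pairs(r, "gazing", "any")
    expect_equal(nrow(ep), length(never) * 9)
    got <- unique(paste(ep$member_a, ep$member_b))
    expect_setequal(got, never)
    # no pseudo pairing duplicates a real partnership
    expect_length(intersect(got, real), 0)

    # round_matched oracle: per round, all combos minus that round's dyads
    em <- enumerate_pseudo_pairs(r, "gazing", "round_matched")
    expected <- sum(vapply(split(r, r$round), function(rr) {
      choose(length(unique(c(rr$member_a, rr$member_b))), 2) - nrow(rr)
    }, numeric(1)))
    expect_equal(nrow(em), expected)
    expect_true(all(em$round_a == em$round_b))
  }
})

test_that("unknown condition labels are rejected", {
  r <- make_roster(4, 1, "gazing", seed = 1)
  expect_error(enumerate_pseudo_pairs(r, "jlm"), "unknown condition")
})

test_that("synchrony table has the expected real and pseudo row counts", {
  cfg <- sim_config(n_participants = 6, n_rounds = 2, conditions = "gazing",
                    duration_s = 60, nonsmiler_prob = 0, seed = 5)
  b <- simulate_study(cfg)
  st <- synchrony_table(b, "smile", scope = "any")
  expect_equal(sum(st$pair_type == "real"), 6)
  n_pseudo_expected <- nrow(enumerate_pseudo_pairs(b$roster, "gazing", "any"))
  expect_equal(sum(st$pair_type == "pseudo"), n_pseudo_expected)
  expect_true(all(st$eligible))
  expect_equal(attr(st, "scope"), "any")
  expect_length(attr(st, "skipped"), 0)

  # capping draws a deterministic subsample
  st_cap <- synchrony_table(b, "smile", scope = "any", max_pseudo_pairs = 5,
                            seed = 3)
  expect_equal(sum(st_cap$pair_type == "pseudo"), 5)
  st_cap2 <- synchrony_table(b, "smile", scope = "any", max_pseudo_pairs = 5,
                             seed = 3)
  expect_identical(st_cap$pair_id, st_cap2$pair_id)
})

test_that("real pairs out-synchronize pseudo pairs under strong coupling", {
  cfg <- sim_config(n_participants = 8, n_rounds = 2, conditions = "gazing",
                    duration_s = 120, nonsmiler_prob = 0,
                    mimicry_prob = 0.9, hr_coupling = 0.9, seed = 21)
  b <- simulate_study(cfg)
  st <- synchrony_table(b, "smile", scope = "any")
  real <- st$r[st$pair_type == "real" & !is.na(st$r)]
  pseudo <- st$r[st$pair_type == "pseudo" & !is.na(st$r)]
  expect_gt(mean(real), mean(pseudo) + 0.1)

  sth <- synchrony_table(b, "hr", scope = "round_matched")
  realh <- sth$r[sth$pair_type == "real" & !is.na(sth$r)]
  pseudoh <- sth$r[sth$pair_type == "pseudo" & !is.na(sth$r)]
  expect_gt(mean(realh), mean(pseudoh) + 0.2)
  # HR means are reported on the bpm scale even after prewhitening
  expect_true(all(sth$mean_pair > 40))
})

test_that("the familiarity filter removes familiar dyads from both arms", {
  cfg <- sim_config(n_participants = 8, n_rounds = 2, conditions = "gazing",
                    duration_s = 40, nonsmiler_prob = 0,
                    familiarity_prob = 0.4, seed = 8)
  b <- simulate_study(cfg)
  familiar <- b$roster$dyad_id[b$roster$familiar_a > 0 |
                                 b$roster$familiar_b > 0]
  # the fixture must exercise both branches of the filter
  expect_gt(length(familiar), 0)
  expect_lt(length(familiar), nrow(b$roster))
  st <- synchrony_table(b, "smile", exclude_familiar = TRUE)
  expect_length(intersect(st$pair_id, familiar), 0)
  expect_gt(nrow(st), 0)

  # an all-familiar roster yields an empty, well-formed table
  b2 <- b
  b2$roster$familiar_a <- 1L
  st2 <- synchrony_table(b2, "smile", exclude_familiar = TRUE)
  expect_equal(nrow(st2), 0)
})

test_that("ineligible non-smiler pairings are recorded, not dropped", {
  cfg <- sim_config(n_participants = 4, n_rounds = 1, conditions = "gazing",
                    duration_s = 40, nonsmiler_prob = 1, seed = 2)
  b <- simulate_study(cfg)
  st <- synchrony_table(b, "smile")
  expect_true(all(!st$eligible))
  expect_true(all(is.na(st$r)))
  expect_true(all(grepl("non-smiler", st$exclusion_reason)))
  expect_gt(sum(attr(st, "exclusions")), 0)
})
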