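ratings_fixture <- function() {
  tibble::tibble(
    rater_id = sprintf("p%02d", 1:6),
    partner_id = sprintf("p%02d", c(2, 1, 4, 3, 6, 5)),
    dyad_id = rep(c("d1", "d2", "d3"), each = 2),
    round = 1L,
    condition = rep(c("gazing", "gazing", "jlm"), each = 2)[1:6],
    measure = "closeness",
    pre = c(2, 3, 4, 5, 3, 1),
    post = c(4, 4, 5, 7, 3, 2),
    familiarity = 0L
  )
}

test_that("standardize scales pre/post by the pre-exercise mean and SD", {
  r <- ratings_fixture()
  s <- standardize(r, "closeness")
  mu <- mean(r$pre)
  sdv <- sd(r$pre)
  expect_equal(s$pre, (r$pre - mu) / sdv, tolerance = 1e-12)
  expect_equal(s$post, (r$post - mu) / sdv, tolerance = 1e-12)
  sc <- attr(s, "scaling")$closeness$all
  expect_equal(unname(sc), c(mu, sdv))
  # post minus pre is the raw change in pre-SD units
  expect_equal(s$post - s$pre, (r$post - r$pre) / sdv, tolerance = 1e-12)
})

test_that("post-only measures are z-scored and zero SD is rejected", {
  r <- ratings_fixture()
  r$measure <- "dictator_keep"
  r$pre <- NA_real_
  s <- standardize(r, "dictator_keep")
  expect_equal(mean(s$post), 0, tolerance = 1e-12)
  expect_equal(sd(s$post), 1, tolerance = 1e-12)

  r$post <- 5
  expect_error(standardize(r, "dictator_keep"), "zero SD")
  r2 <- ratings_fixture()
  r2$pre <- 4
  expect_error(standardize(r2, "closeness"), "zero pre-exercise SD")
  expect_error(standardize(r2, "warmth"), "measure")
})

test_that("by-condition standardization scales each condition separately", {
  r <- ratings_fixture()
  s <- standardize(r, "closeness", by_condition = TRUE)
  g <- r$condition == "gazing"
  expect_equal(s$pre[g], (r$pre[g] - mean(r$pre[g])) / sd(r$pre[g]),
               tolerance = 1e-12)
})

test_that("dyad change scores average post-minus-pre over both members", {
  r <- ratings_fixture()
  cs <- dyad_change_scores(r)
  expect_equal(nrow(cs), 3)
  expect_equal(cs$change[cs$dyad_id == "d1"], mean(c(4 - 2, 4 - 3)))
  expect_equal(cs$change[cs$dyad_id == "d2"], mean(c(5 - 4, 7 - 5)))
  # incomplete dyads are excluded and reported
  cs2 <- dyad_change_scores(r[-6, ])
  expect_equal(nrow(cs2), 2)
  expect_equal(attr(cs2, "excluded")$dyad_id, "d3")
  # post-only measures use the post value itself
  r3 <- ratings_fixture()
  r3$pre <- NA_real_
  cs3 <- dyad_change_scores(r3)
  expect_equal(cs3$change[cs3$dyad_id == "d1"], 4)
})

test_that("fit_ols is exact on noiseless data and matches lm in general", {
  d <- data.frame(x = 1:10)
  d$y <- 3 + 2 * d$x
  f <- fit_ols(y ~ x, d)
  expect_equal(f$estimate, c(3, 2), tolerance = 1e-10)
  expect_true(attr(f, "zero_residual"))

  set.seed(51)
  for (i in 1:20) {
    n <- sample(15:40, 1)
    dd <- data.frame(x1 = rnorm(n), x2 = rnorm(n),
                     g = factor(sample(c("a", "b"), n, replace = TRUE)))
    dd$y <- 1 + 0.5 * dd$x1 - dd$x2 + (dd$g == "b") + rnorm(n)
    mine <- fit_ols(y ~ x1 + x2 + g, dd)
    ref <- summary(lm(y ~ x1 + x2 + g, dd))$coefficients
    expect_equal(mine$estimate, unname(ref[, 1]), tolerance = 1e-10)
    expect_equal(mine$se, unname(ref[, 2]), tolerance = 1e-10)
    expect_equal(mine$p_value, unname(ref[, 4]), tolerance = 1e-10)
    expect_equal(unique(mine$df), n - 4)
  }
})

test_that("fit_ols names the collinear terms when the design is singular", {
  d <- data.frame(x = 1:10, z = 2 * (1:10), y = rnorm(10))
  expect_error(fit_ols(y ~ x + z, d), "collinear terms: z")
  expect_error(fit_ols(y ~ x, d[1:2, ]), "no residual degrees of freedom")
})

test_that("mixed model with null grouping collapses to OLS", {
  set.seed(52)
  d <- data.frame(x = rnorm(40), participant = factor(rep(1:40)),
                  dyad = factor(rep(1:20, each = 2)))
  d$y <- 1 + 2 * d$x + rnorm(40)
  # participant has 40 singleton levels and dyad variance is truly 0:
  # both should be pruned and the fit collapse to OLS
  f <- fit_dyadic_mixed(y ~ x, d, random = c("participant", "dyad"))
  ols <- fit_ols(y ~ x, d)
  expect_equal(attr(f, "engine"), "ols")
  expect_equal(f$estimate, ols$estimate, tolerance = 1e-8)
  expect_true(length(attr(f, "pruning_path")) >= 1)
})

test_that("mixed model recovers fixed effect and variance components", {
  set.seed(53)
  n_part <- 50
  n_rep <- 4
  d <- data.frame(participant = factor(rep(1:n_part, each = n_rep)))
  u <- rnorm(n_part, 0, 1.5) # participant intercepts, variance 2.25
  d$x <- rnorm(nrow(d))
  d$y <- 1 + 0.5 * d$x + u[as.integer(d$participant)] + rnorm(nrow(d), 0, 1)
  f <- fit_dyadic_mixed(y ~ x, d, random = "participant")
  expect_equal(attr(f, "engine"), "lmer")
  est <- f$estimate[f$term == "x"]
  se <- f$se[f$term == "x"]
  expect_lt(abs(est - 0.5), 2 * se)
  vc <- attr(f, "variance_components")
  expect_lt(abs(vc[["participant"]] - 2.25) / 2.25, 0.4)
  expect_lt(abs(vc[["Residual"]] - 1), 0.3)
  expect_equal(attr(f, "random_retained"), "participant")
})

test_that("single-level grouping factors are dropped up front", {
  set.seed(54)
  d <- data.frame(x = rnorm(30), round = 1L,
                  participant = factor(rep(1:10, 3)))
  d$y <- d$x + rnorm(30) + rnorm(10)[as.integer(d$participant)]
  f <- fit_dyadic_mixed(y ~ x, d, random = c("participant", "round"))
  expect_true(any(grepl("single level", attr(f, "pruning_path"))))
  expect_error(fit_dyadic_mixed(y ~ x, d, random = "dyad"),
               "grouping columns not in data")
})

test_that("identical arms give t = 0, p = 1 and the Bonferroni threshold", {
  vals <- c(0.1, 0.2, 0.3, 0.4)
  st <- tibble::tibble(
    condition = rep(c("gazing", "jlm"), each = 8),
    pair_type = rep(rep(c("real", "pseudo"), each = 4), 2),
    r = rep(vals, 4)
  )
  tests <- pair_vs_pseudo_tests(st)
  expect_equal(nrow(tests), 3) # 2 within-condition + 1 between
  expect_equal(tests$statistic, rep(0, 3))
  expect_equal(tests$p_value, rep(1, 3))
  expect_equal(unique(tests$threshold), 0.05 / 3)
  expect_false(any(tests$significant))

  # three conditions give the standard six-contrast family and 0.05/6
  st3 <- dplyr::bind_rows(st, tibble::tibble(
    condition = "eyes_closed", pair_type = rep(c("real", "pseudo"), each = 4),
    r = rep(vals, 2)
  ))
  t3 <- pair_vs_pseudo_tests(st3)
  expect_equal(nrow(t3), 6)
  expect_equal(round(unique(t3$threshold), 3), 0.008)
})

test_that("pair-vs-pseudo tests match t.test and reject tiny arms", {
  set.seed(55)
  st <- tibble::tibble(
    condition = "gazing",
    pair_type = rep(c("real", "pseudo"), c(10, 30)),
    r = c(rnorm(10, 0.4, 0.1), rnorm(30, 0.05, 0.1))
  )
  out <- pair_vs_pseudo_tests(st)
  ref <- t.test(st$r[st$pair_type == "real"], st$r[st$pair_type == "pseudo"],
                var.equal = TRUE)
  expect_equal(out$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(out$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(out$df, 38)
  expect_true(out$significant)
  # undefined r rows (ineligible pairs) are dropped before testing
  st_na <- dplyr::bind_rows(st, tibble::tibble(condition = "gazing",
                                               pair_type = "real", r = NA))
  expect_equal(pair_vs_pseudo_tests(st_na)$n1, 10)

  tiny <- tibble::tibble(condition = "gazing",
                         pair_type = c("real", "pseudo", "pseudo"),
                         r = c(0.5, 0.1, 0.2))
  expect_error(pair_vs_pseudo_tests(tiny), "fewer than 2 observations")
})

test_that("hr change model handles degenerate, independent and repeated designs", {
  # constant change across recordings: degenerate engine, exact estimate
  d0 <- tibble::tibble(participant = sprintf("p%d", 1:6),
                       condition = "gazing", change = -10)
  m0 <- hr_change_model(d0)
  expect_equal(m0$engine, "degenerate")
  expect_equal(m0$estimate, -10)
  expect_equal(m0$se, 0)

  # one recording per participant: equivalent to a one-sample t-test
  set.seed(56)
  d1 <- tibble::tibble(participant = sprintf("p%d", 1:20),
                       condition = "gazing", change = rnorm(20, -8, 2))
  m1 <- hr_change_model(d1)
  ref <- t.test(d1$change)
  expect_equal(m1$engine, "t-test")
  expect_equal(m1$estimate, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(m1$p_value, ref$p.value, tolerance = 1e-12)

  # repeated participation with real between-participant spread: lmer
  set.seed(57)
  u <- rnorm(15, 0, 2)
  d2 <- tibble::tibble(
    participant = rep(sprintf("p%d", 1:15), each = 4),
    condition = "jlm",
    change = -9 + rep(u, each = 4) + rnorm(60)
  )
  m2 <- hr_change_model(d2)
  expect_equal(m2$engine, "lmer")
  expect_lt(abs(m2$estimate - (-9)), 2 * m2$se + 1)
  expect_equal(m2$n, 60)
})
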