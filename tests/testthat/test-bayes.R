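spec_fast <- bayesSpec(n_draws = 2000L, n_tune = 500L, chains = 2L, seed = 1L)

test_that("hdi matches closed forms for known distributions", {
  set.seed(1)
  z <- rnorm(1e5)
  h <- hdi(z)
  expect_equal(h[1], -1.96, tolerance = 0.05)
  expect_equal(h[2], 1.96, tolerance = 0.05)
  e <- rexp(1e5)
  he <- hdi(e)
  expect_equal(he[1], 0, tolerance = 0.05)
  expect_equal(he[2], -log(0.05), tolerance = 0.05)
  expect_equal(hdi(rep(3.2, 500)), c(3.2, 3.2))
  expect_error(hdi(z, mass = 1.2), "mass")
  # symmetric unimodal draws: hdi agrees with the equal-tailed interval
  expect_equal(h, unname(quantile(z, c(0.025, 0.975))), tolerance = 0.05)
})

test_that("p_difference reports the majority side of zero", {
  expect_equal(pDifference(rep(1, 200)), 100)
  expect_equal(pDifference(c(rep(1, 943), rep(-1, 57))), 94.3)
  set.seed(2)
  z <- rnorm(1e5)
  expect_equal(pDifference(z), 50, tolerance = 0.5)
  expect_equal(pDifference(-z), pDifference(z))
  expect_equal(pDifference(c(0, 0, 1, -1)), 50)
  expect_error(pDifference(numeric(0)), "no draws")
})

test_that("the 2x2 model recovers injected effects and the null", {
  set.seed(3)
  null <- make_long()
  f0 <- fitGroupTimeModel(null, spec_fast)
  s0 <- f0$summary
  eff <- s0[s0$parameter %in% c("group", "time", "interaction"), ]
  expect_true(all(abs(eff$mean) < 3 * 0.1 * sqrt(4 / 17)))
  expect_true(all(s0$rhat < 1.05, na.rm = TRUE))

  set.seed(4)
  errs <- sapply(1:5, function(i) {
    d <- make_long(group_eff = 0.1, time_eff = 0.05, interaction = 0.09)
    f <- fitGroupTimeModel(d, spec_fast)
    f$summary$mean[f$summary$parameter == "interaction"] - 0.09
  })
  expect_lt(mean(abs(errs)), 0.05)
})

test_that("samplers are exactly reproducible given a seed", {
  set.seed(5)
  d <- make_long(group_eff = 0.2)
  a <- fitGroupTimeModel(d, spec_fast)
  b <- fitGroupTimeModel(d, spec_fast)
  expect_identical(a$draws, b$draws)
})

test_that("posterior predictive checks pass on model-generated data", {
  set.seed(6)
  flags <- sapply(1:8, function(i) {
    d <- make_long(group_eff = 0.1, sd = 0.1)
    f <- fitGroupTimeModel(d, bayesSpec(n_draws = 1500, n_tune = 400,
                                        chains = 2, seed = i,
                                        rhat_threshold = 1.05))
    sum(posteriorPredictiveCheck(f, n_rep = 300)$flag)
  })
  expect_gte(sum(flags == 0), 6) # flag-free in the large majority of runs
})

test_that("posterior predictive checks flag heavy-tail contamination", {
  set.seed(7)
  d <- make_long(sd = 0.05)
  bad <- sample(nrow(d), 6)
  d$value[bad] <- d$value[bad] + rt(6, df = 1) * 0.5
  f <- fitGroupTimeModel(d, spec_fast)
  ppc <- posteriorPredictiveCheck(f, n_rep = 400)
  expect_gt(sum(ppc$flag[ppc$statistic == "sd"]), 0)
})

test_that("replicated cell means track observed cell means", {
  set.seed(8)
  d <- make_long(group_eff = 0.15, time_eff = 0.05)
  f <- fitGroupTimeModel(d, spec_fast)
  ppc <- posteriorPredictiveCheck(f, n_rep = 400)
  mm <- ppc[ppc$statistic == "mean", ]
  expect_lt(max(abs(mm$replicated_mean - mm$observed)), 0.05)
})

test_that("regression recovers a known slope and rejects flat covariates", {
  set.seed(9)
  x <- seq(10, 34, length.out = 17)
  y <- 2 * x + rnorm(17, 0, 0.1)
  r <- bayesianRegression(y, x, spec_fast)
  expect_equal(r$mean[r$parameter == "slope"], 2, tolerance = 0.1)
  expect_gt(r$p_difference[r$parameter == "slope"], 99)
  # null slope: HDI straddles zero
  y0 <- rnorm(17, 1, 0.2)
  r0 <- bayesianRegression(y0, x, spec_fast)
  expect_lt(r0$hdi_low[r0$parameter == "slope"], 0)
  expect_gt(r0$hdi_high[r0$parameter == "slope"], 0)
  expect_error(bayesianRegression(y, rep(2, 17), spec_fast), "variance")
  expect_error(bayesianRegression(y[1:3], x[1:3], spec_fast), "at least 5")
})

test_that("posterior is insensitive to widening the already-wide priors", {
  set.seed(10)
  d <- make_long(group_eff = 0.1, interaction = 0.09)
  a <- fitGroupTimeModel(d, bayesSpec(n_draws = 4000, n_tune = 500,
                                      chains = 2, seed = 2, prior_scale = 10))
  b <- fitGroupTimeModel(d, bayesSpec(n_draws = 4000, n_tune = 500,
                                      chains = 2, seed = 2,
                                      prior_scale = 100))
  am <- a$summary$mean[a$summary$parameter %in% c("group", "interaction")]
  bm <- b$summary$mean[b$summary$parameter %in% c("group", "interaction")]
  expect_lt(max(abs(am - bm)), 0.02)
})

test_that("likelihood comparison separates normal from heavy-tailed data", {
  set.seed(11)
  d <- make_long(sd = 0.1)
  lc <- likelihoodComparison(d, spec_fast, n_dic = 800)
  expect_true(lc$preferred == "normal" || abs(lc$difference) < 2)
  # identical inputs give identical criteria at a fixed seed
  lc2 <- likelihoodComparison(d, spec_fast, n_dic = 800)
  expect_identical(lc$difference, lc2$difference)
  set.seed(12)
  dt_ <- make_long(sd = 0.001)
  dt_$value <- dt_$value + 0.1 * rt(nrow(dt_), df = 2)
  lct <- likelihoodComparison(dt_, spec_fast, n_dic = 800)
  expect_equal(lct$preferred, "t")
})

test_that("malformed 2x2 inputs are rejected", {
  d <- make_long()
  expect_error(fitGroupTimeModel(d[d$group == "control", ], spec_fast),
               "two groups")
  tiny <- d[c(1, 19, 36, 54, 71), ]
  expect_error(fitGroupTimeModel(tiny, spec_fast), "at least 2")
  expect_error(bayesSpec(n_draws = 100), "1000")
})
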