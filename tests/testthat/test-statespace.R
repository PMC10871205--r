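sched <- phaseSchedule()

test_that("forward simulations match independent stride-loop oracles", {
  g <- splitbelt:::modelGrid(sched)
  set.seed(11)
  for (i in 1:25) {
    p <- random_vc_params()
    orc <- oracle_vc(p[["Afast"]], p[["Bfast"]], p[["Aslow"]], p[["Bslow"]],
                     p[["Bexplicit"]], g$pert, g$fb)
    tr <- simulateVC(p, sched)
    expect_lt(max(abs(tr$x - orc$x)), 1e-12)
    expect_lt(max(abs(tr$xexplicit - orc$xexplicit)), 1e-12)

    trd <- simulateDualRate(p[1:4], sched)
    orcd <- oracle_vc(p[["Afast"]], p[["Bfast"]], p[["Aslow"]], p[["Bslow"]],
                      0, g$pert, g$fb)
    expect_lt(max(abs(trd$x - orcd$x)), 1e-12)

    A <- runif(1); B <- runif(1)
    trs <- simulateSingleRate(c(A = A, B = B), sched)
    expect_lt(max(abs(trs$x - oracle_single(A, B, g$pert))), 1e-12)
  }
})

test_that("one-step recursion from the canonical initialisation values", {
  tr <- simulateVC(vcParams(0.92, 0.03, 0.996, 0.004, 0.2), sched)
  # stride 2: error[1] = 1, so x = Bfast + Bslow + Bexplicit
  expect_equal(tr$x[2], 0.03 + 0.004 + 0.2)
  expect_equal(tr$xexplicit[1], 0) # no prior error on the first stride
})

test_that("explicit state is feedback-gated and memoryless", {
  p <- vcParams(0, 0, 0, 0, Bexplicit = 0.2)
  tr <- simulateVC(p, sched)
  # implicit states stay 0, error pinned at 1 -> output = Bexplicit on
  # every feedback stride after the first, and 0 immediately after offset
  expect_equal(tr$x[2:40], rep(0.2, 39))
  expect_equal(tr$x[1], 0)
  expect_equal(tr$x[41:60], rep(0, 20))
})

test_that("output drops by the prior explicit state at feedback offset", {
  p <- vcParams(Bexplicit = 0.3)
  base <- simulateVC(p, sched)
  extended <- simulateVC(p, phaseSchedule(feedback_window = c(1L, 41L)))
  # histories agree through stride 40; the counterfactual keeps feedback
  # on at stride 41, so the observed drop is exactly its explicit state
  expect_equal(extended$x[41] - base$x[41], extended$xexplicit[41])
  expect_gt(extended$xexplicit[41], 0)
})

test_that("output decomposes as explicit plus implicit on every stride", {
  set.seed(21)
  for (i in 1:10) {
    tr <- simulateVC(random_vc_params(), sched)
    expect_lt(max(abs(tr$x - tr$xexplicit - tr$ximplicit)), 1e-14)
    expect_true(all(tr$xexplicit[!tr$feedback_on] == 0))
  }
})

test_that("models nest: vc(Bexplicit=0) = dual; degenerate dual = single", {
  p <- random_vc_params()
  p[["Bexplicit"]] <- 0
  expect_equal(simulateVC(p, sched)$x, simulateDualRate(p[1:4], sched)$x)
  # one process zeroed, equal retention -> single-rate with B = Bfast
  d <- simulateDualRate(c(Afast = 0.9, Bfast = 0.05, Aslow = 0.9001,
                          Bslow = 0), sched)
  s <- simulateSingleRate(c(A = 0.9, B = 0.05), sched)
  expect_lt(max(abs(d$x - s$x)), 1e-3) # Aslow differs by the epsilon margin
  expect_equal(simulateDualRate(c(Afast = 0.5, Bfast = 0, Aslow = 0.9,
                                  Bslow = 0), sched)$x,
               rep(0, nrow(d)))
})

test_that("implicit output stays bounded in the stable parameter regime", {
  # the two-state error loop is only stable when its closed-loop matrix
  # has spectral radius < 1; within that regime the output is bounded by
  # 1 + Bfast + Bslow above and the washout undershoot by -(Bfast + Bslow)
  set.seed(31)
  tested <- 0
  while (tested < 20) {
    p <- random_vc_params()
    M <- rbind(c(p[["Afast"]] - p[["Bfast"]], -p[["Bfast"]]),
               c(-p[["Bslow"]], p[["Aslow"]] - p[["Bslow"]]))
    if (max(abs(eigen(M, only.values = TRUE)$values)) >= 1) next
    tested <- tested + 1
    tr <- simulateVC(p, sched)
    b <- p[["Bfast"]] + p[["Bslow"]]
    expect_true(all(tr$ximplicit >= -b - 1e-12))
    expect_true(all(tr$ximplicit <= 1 + b + 1e-12))
  }
})

test_that("single-rate fixed point is B/(1-A+B) under sustained perturbation", {
  long <- phaseSchedule(adaptation = 5000L, deadaptation = 2L)
  for (A in c(0.5, 0.9, 0.99)) for (B in c(0.05, 0.2)) {
    tr <- simulateSingleRate(c(A = A, B = B), long)
    expect_equal(tr$x[5000], B / (1 - A + B), tolerance = 1e-6)
  }
  frozen <- simulateSingleRate(c(A = 1, B = 0), sched)
  expect_equal(unique(frozen$x), 0)
  # A = 0, B = 1: x[s+1] = error[s], alternating 0,1,0,1,...
  relay <- simulateSingleRate(c(A = 0, B = 1), sched)
  expect_equal(relay$x[1:5], c(0, 1, 0, 1, 0))
})
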