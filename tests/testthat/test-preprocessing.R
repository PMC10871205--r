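test_that("step length asymmetry is the normalised percent difference", {
  cases <- list(c(50, 50, 0), c(60, 40, 20), c(40, 60, -20))
  for (cs in cases)
    expect_equal(stepLengthAsymmetry(cs[1], cs[2]), cs[3])
  expect_error(stepLengthAsymmetry(1, -1), "non-zero")
})

test_that("baseline correction removes the Baseline mean and is idempotent", {
  s <- make_asym(rep(c("Baseline", "Adaptation", "Deadaptation"), each = 10),
                 rep(5, 30))
  out <- baselineCorrect(s)
  expect_equal(out$sla, rep(0, 30))
  s2 <- make_asym(rep(c("Baseline", "Adaptation", "Deadaptation"),
                      c(10, 10, 10)),
                  c(rep(2, 10), rep(-18, 10), rep(1, 10)))
  out2 <- baselineCorrect(s2)
  expect_equal(out2$sla[11], -20)
  expect_equal(baselineCorrect(out2)$sla, out2$sla)
  expect_equal(mean(out2$sla[out2$phase == "Baseline"]), 0)
  expect_error(baselineCorrect(make_asym(rep("Adaptation", 5), 1:5)),
               "Baseline")
})

test_that("3x IQR fence removes extreme strides and only those", {
  s <- make_asym(rep("Baseline", 50), c(rep(0, 49), 100))
  out <- suppressWarnings(removeOutliers(s)) # zero IQR is degenerate here
  expect_false(out$retained[50])
  expect_true(all(out$retained[1:49]))
  expect_equal(attr(out, "removed_fraction"), 2)
  expect_equal(attr(out, "outlier_fraction"), 2)

  same <- make_asym(rep("Baseline", 20), rep(3, 20))
  expect_warning(out2 <- removeOutliers(same), "IQR")
  expect_true(all(out2$retained))

  set.seed(5)
  noisy <- make_asym(rep("Baseline", 200), rnorm(200))
  out3 <- removeOutliers(noisy)
  q <- quantile(noisy$sla, c(0.25, 0.75), names = FALSE)
  fence <- c(q[1] - 3 * diff(q), q[2] + 3 * diff(q))
  inside <- noisy$sla >= fence[1] & noisy$sla <= fence[2]
  expect_equal(out3$retained, inside)
  expect_equal(attr(out3, "removed_fraction"), 100 * mean(!inside))
})

test_that("first-stride removal drops one stride per phase, idempotently", {
  s <- make_asym(rep(c("Baseline", "Adaptation", "Deadaptation"), each = 10),
                 rnorm(30))
  out <- dropFirstStrides(s)
  expect_equal(sum(out$retained), 27)
  expect_equal(dropFirstStrides(out)$retained, out$retained)
  expect_equal(out$phase, s$phase)
  expect_error(dropFirstStrides(make_asym(c("Baseline", "Adaptation"),
                                          c(0, 1))),
               "at least 2")
})

test_that("Adaptation Index anchors 0 at the perturbation and 1 at recovery", {
  sla <- c(rep(0, 5), # Baseline
           seq(-20, -2, length.out = 12), # Adaptation, min of first 10 = -20
           seq(15, 1, length.out = 12)) # Deadaptation, max of first 10 = 15
  s <- make_asym(rep(c("Baseline", "Adaptation", "Deadaptation"),
                     c(5, 12, 12)), sla, baseline_corrected = TRUE)
  out <- suppressWarnings(adaptationIndex(s))
  pert <- attr(out, "perturbation")
  expect_equal(unname(pert), c(-20, 15))
  iA <- out$phase == "Adaptation"
  expect_equal(out$ai[iA][1], 0) # stride at the perturbation
  expect_equal(out$ai[which(iA & abs(out$sla) < 1e-9)], numeric(0)) # none at 0
  expect_equal(out$ai[iA], (sla[6:17] + 20) / 20)
  iD <- out$phase == "Deadaptation"
  expect_equal(out$ai[iD], sla[18:29] / 15)
  expect_equal(out$ai[iD][1], 1) # the aftereffect peak
  expect_true(all(is.na(out$ai[out$phase == "Baseline"])))
  expect_equal(out$condition, as.numeric(out$phase == "Adaptation"))
})

test_that("Adaptation Index handles degenerate and short phases", {
  s <- make_asym(rep(c("Adaptation", "Deadaptation"), each = 12),
                 rep(0, 24), baseline_corrected = TRUE)
  expect_error(suppressWarnings(adaptationIndex(s)), "perturbation is zero")
  short <- make_asym(rep(c("Adaptation", "Deadaptation"), c(20, 6)),
                     c(seq(-20, -1, length.out = 20), rep(5, 6)),
                     baseline_corrected = TRUE)
  expect_warning(adaptationIndex(short), "fewer than 10")
  uncorrected <- make_asym(rep(c("Adaptation", "Deadaptation"), each = 12),
                           rnorm(24))
  expect_error(adaptationIndex(uncorrected), "baseline-corrected")
})

test_that("AI is invariant to a constant shift applied before correction", {
  set.seed(9)
  sla <- c(rnorm(20, 2), rnorm(30, -18, 2), rnorm(30, 10, 2))
  ph <- rep(c("Baseline", "Adaptation", "Deadaptation"), c(20, 30, 30))
  run <- function(x) {
    s <- make_asym(ph, x)
    suppressWarnings(
      adaptationIndex(dropFirstStrides(removeOutliers(baselineCorrect(s)))))
  }
  a <- run(sla)
  b <- run(sla + 7.3)
  expect_equal(a$ai, b$ai)
  expect_equal(a$retained, b$retained)
})

test_that("noise-free pipeline reproduces the latent trajectory", {
  p <- simulateParticipant(vcParams(0.92, 0.03, 0.996, 0.004, 0.2),
                           noise_sd = 0, seed = 1)
  ai <- preprocess(p)
  lat <- attr(p, "latent")
  keep <- ai$retained & is.finite(ai$ai)
  expect_lt(max(abs(ai$ai[keep] - lat$ai[keep])), 1e-8)
  # and against the hand-coded normalisation oracle on the latent asymmetry
  ret <- lat$stride != 1L
  expect_lt(max(abs(ai$ai[keep] -
                    oracle_ai(lat$phase, lat$sla, ret)[keep])), 1e-8)
})

test_that("round trip through CSV preserves the stride record", {
  dir <- withr::local_tempdir()
  coh <- simulateCohort(cohortConfig(n = c(control = 2L, stroke = 1L),
                                     seed = 4L))
  writeCohortCSV(coh, dir)
  back <- readCohortCSV(dir)
  expect_setequal(names(back$participants), names(coh$participants))
  p0 <- coh$participants[[1]]
  p1 <- back$participants[[p0$participant_id[1]]]
  expect_equal(p1$fast_step_cm, p0$fast_step_cm, tolerance = 1e-12)
  expect_equal(p1$feedback_on, p0$feedback_on)
  expect_equal(back$truth$Bexplicit, coh$truth$Bexplicit, tolerance = 1e-12)
})
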