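#' Simulate one participant's stride-by-stride step lengths
#'
#' Generates a full Baseline / Adaptation / De-adaptation step-length
#' record whose Adaptation Index follows the voluntary-correction model.
#' The latent model output `x` is simulated with [simulateVC()], then
#' mapped back to step length asymmetry (%): during Adaptation
#' `sla = x*|P| + P` (so `x = 0` leaves the full perturbation `P` and
#' `x = 1` restores symmetry), during De-adaptation `sla = x*|P|` (the
#' aftereffect, decaying to 0), and during Baseline `sla = 0`. Zero-mean
#' Gaussian stride noise with SD `noise_sd * |P|` (i.e. `noise_sd` in
#' Adaptation Index units) is added on the asymmetry scale, and fast/slow
#' step lengths are reconstructed holding `fast + slow = baseline_total`.
#'
#' Optionally, strides are replaced (with probability `outlier_rate`)
#' by values thrown beyond the participant's own 3x IQR fence, emulating
#' the aberrant strides the cleaning stage is designed to catch.
#'
#' @param params A [vcParams()] set (use `Bexplicit = 0` for a purely
#'   implicit learner).
#' @param schedule A [phaseSchedule()].
#' @param noise_sd Stride noise SD in Adaptation Index units.
#' @param perturbation_pct Step-length asymmetry (%) induced by the split
#'   belts; negative under the usual fast/slow convention. Must be
#'   non-zero.
#' @param baseline_total Sum of fast and slow step lengths (cm).
#' @param outlier_rate Per-stride probability of an injected outlier.
#' @param seed Optional integer seed.
#' @param id,group Participant identifier and group label.
#' @param covariate Optional clinical covariate (e.g. a Lower Extremity
#'   Fugl-Meyer score, points).
#' @return A `stride_series` data frame with columns `participant_id`,
#'   `group`, `phase`, `stride`, `fast_step_cm`, `slow_step_cm`,
#'   `feedback_on`, and attributes `latent` (noise-free `phase`, `stride`,
#'   `x`, `sla`, `ai` — the `ai` uses the same first-stride-dropped,
#'   first-10-retained normalisation the preprocessing applies),
#'   `schedule`, `params`, `covariate`, `outliers` (injected stride rows).
#' @examples
#' p <- simulateParticipant(vcParams(Bexplicit = 0.2), noise_sd = 0, seed = 1)
#' head(p)
#' @export
simulateParticipant <- function(params, schedule = phaseSchedule(),
                                noise_sd = 0.05, perturbation_pct = -20,
                                baseline_total = 120, outlier_rate = 0,
                                seed = NULL, id = "P01", group = "control",
                                covariate = NA_real_) {
  p <- asParamVector(params, c("Afast", "Bfast", "Aslow", "Bslow", "Bexplicit"))
  if (any(p < 0 | p > 1)) stop("parameters must lie in [0, 1]")
  if (!is.finite(perturbation_pct) || perturbation_pct == 0)
    stop("perturbation_pct must be non-zero (normalisation is degenerate)")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  traj <- simulateVC(p, schedule)
  aP <- abs(perturbation_pct)
  nB <- schedule$phases[["Baseline"]]

  phase <- c(rep("Baseline", nB), traj$phase)
  stride <- c(seq_len(nB), traj$stride)
  x <- c(rep(NA_real_, nB), traj$x)
  sla_true <- c(rep(0, nB),
                ifelse(traj$phase == "Adaptation",
                       traj$x * aP + perturbation_pct, traj$x * aP))
  n <- length(sla_true)
  sla <- sla_true + stats::rnorm(n, 0, noise_sd * aP)

  out_idx <- integer(0)
  if (outlier_rate > 0) {
    hit <- stats::runif(n) < outlier_rate
    out_idx <- which(hit)
    if (length(out_idx)) {
      q <- stats::quantile(sla, c(0.25, 0.75), names = FALSE)
      iqr <- q[2] - q[1]
      up <- stats::runif(length(out_idx)) < 0.5
      jump <- stats::runif(length(out_idx), 0.5, 2) * max(iqr, 1)
      sla[out_idx] <- ifelse(up, q[2] + 3 * iqr + jump,
                             q[1] - 3 * iqr - jump)
    }
  }

  fb <- c(rep(FALSE, nB), traj$feedback_on)
  out <- data.frame(participant_id = id, group = group, phase = phase,
                    stride = stride,
                    fast_step_cm = baseline_total * (1 + sla / 100) / 2,
                    slow_step_cm = baseline_total * (1 - sla / 100) / 2,
                    feedback_on = fb, stringsAsFactors = FALSE)
  # latent AI under the pipeline's own convention (first stride of each
  # phase dropped before the first-10-stride perturbation estimate)
  ret <- stride != 1L
  latent_ai <- rep(NA_real_, n)
  pertOf <- function(ph, f) {
    i <- which(phase == ph & ret)
    f(sla_true[i[seq_len(min(10L, length(i)))]])
  }
  pA <- pertOf("Adaptation", min)
  pD <- pertOf("Deadaptation", max)
  if (pA != 0)
    latent_ai[phase == "Adaptation"] <-
      (sla_true[phase == "Adaptation"] - pA) / abs(pA)
  if (pD != 0)
    latent_ai[phase == "Deadaptation"] <-
      sla_true[phase == "Deadaptation"] / abs(pD)
  attr(out, "latent") <- data.frame(phase = phase, stride = stride, x = x,
                                    sla = sla_true, ai = latent_ai,
                                    stringsAsFactors = FALSE)
  attr(out, "schedule") <- schedule
  attr(out, "params") <- p
  attr(out, "participant_id") <- id
  attr(out, "group") <- group
  attr(out, "covariate") <- covariate
  attr(out, "outliers") <- out_idx
  class(out) <- c("stride_series", "data.frame")
  out
}

#' Configuration for a two-group synthetic cohort
#'
#' Bundles the generative settings for [simulateCohort()]. Each group has
#' mean and SD for the five voluntary-correction rates; per-participant
#' parameters are drawn from normals truncated to \[0, 1\] and then
#' projected onto the identifiability constraints
#' (`Bfast >= 5*Bslow`, `Aslow >= Afast`).
#'
#' The default groups emulate a control-like cohort (substantial explicit
#' learning, high fast-state retention) and a stroke-like cohort (reduced
#' `Bexplicit` and `Afast`), with a Lower Extremity Fugl-Meyer style
#' covariate attached to the stroke-like group.
#'
#' @param n Named integer vector: participants per group.
#' @param means,sds Named list (one element per group) of length-5 named
#'   vectors over `Afast, Bfast, Aslow, Bslow, Bexplicit`.
#' @param noise_sd Stride noise SD (Adaptation Index units).
#' @param perturbation_pct Split-belt perturbation (% asymmetry, non-zero).
#' @param baseline_total Fast + slow step length (cm).
#' @param outlier_rate Per-stride probability of an injected outlier.
#' @param schedule A [phaseSchedule()].
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohortConfig <- function(n = c(control = 18L, stroke = 17L),
                         means = list(
                           control = c(Afast = 0.92, Bfast = 0.03,
                                       Aslow = 0.996, Bslow = 0.004,
                                       Bexplicit = 0.30),
                           stroke = c(Afast = 0.83, Bfast = 0.03,
                                      Aslow = 0.996, Bslow = 0.004,
                                      Bexplicit = 0.07)),
                         sds = list(
                           control = c(Afast = 0.05, Bfast = 0.01,
                                       Aslow = 0.003, Bslow = 0.002,
                                       Bexplicit = 0.10),
                           stroke = c(Afast = 0.05, Bfast = 0.01,
                                      Aslow = 0.003, Bslow = 0.002,
                                      Bexplicit = 0.06)),
                         noise_sd = 0.05, perturbation_pct = -20,
                         baseline_total = 120, outlier_rate = 0,
                         schedule = phaseSchedule(), seed = 1L) {
  if (any(n < 1L)) stop("each group needs at least 1 participant")
  if (!identical(sort(names(n)), sort(names(means))) ||
      !identical(sort(names(n)), sort(names(sds))))
    stop("n, means and sds must name the same groups")
  pn <- c("Afast", "Bfast", "Aslow", "Bslow", "Bexplicit")
  for (g in names(means)) {
    if (!all(pn %in% names(means[[g]])) || !all(pn %in% names(sds[[g]])))
      stop("means and sds need all of: ", paste(pn, collapse = ", "))
    if (any(means[[g]][pn] < 0 | means[[g]][pn] > 1))
      stop("rate means must lie in [0, 1]")
    if (any(sds[[g]][pn] < 0)) stop("rate SDs must be >= 0")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (outlier_rate < 0 || outlier_rate >= 1) stop("outlier_rate must be in [0, 1)")
  structure(list(n = n, means = means, sds = sds, noise_sd = noise_sd,
                 perturbation_pct = perturbation_pct,
                 baseline_total = baseline_total,
                 outlier_rate = outlier_rate, schedule = schedule,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# one truncated-normal draw per element, via the probability transform
rtruncn <- function(n, mean, sd, lo = 0, hi = 1) {
  if (sd == 0) return(rep(mean, n))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate a two-group cohort
#'
#' Draws per-participant voluntary-correction parameters from the group
#' distributions in a [cohortConfig()], simulates every participant with
#' [simulateParticipant()], and records every parameter draw in a truth
#' table for recovery studies. Identical seeds reproduce the cohort
#' bit-for-bit.
#'
#' @param config A [cohortConfig()].
#' @return A list with `participants` (list of `stride_series`) and
#'   `truth` (data frame: `participant_id`, `group`, the five rates,
#'   `covariate`).
#' @examples
#' coh <- simulateCohort(cohortConfig(n = c(control = 2L, stroke = 2L)))
#' coh$truth
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  pn <- c("Afast", "Bfast", "Aslow", "Bslow", "Bexplicit")
  participants <- list()
  truth <- list()
  k <- 0L
  for (g in names(config$n)) {
    for (i in seq_len(config$n[[g]])) {
      k <- k + 1L
      p <- vapply(pn, function(nm)
        rtruncn(1L, config$means[[g]][[nm]], config$sds[[g]][[nm]]), 0)
      # project onto the identifiability constraints
      p[["Bslow"]] <- min(p[["Bslow"]], p[["Bfast"]] / 5)
      p[["Aslow"]] <- min(1, max(p[["Aslow"]], p[["Afast"]] + 1e-4))
      p[["Afast"]] <- min(p[["Afast"]], p[["Aslow"]])
      cov <- if (g == "stroke")
        round(min(34, max(0, 20 + 40 * p[["Bexplicit"]] + stats::rnorm(1, 0, 2))))
      else NA_real_
      id <- sprintf("%s%02d", toupper(substr(g, 1, 1)), i)
      participants[[id]] <- simulateParticipant(
        p, schedule = config$schedule, noise_sd = config$noise_sd,
        perturbation_pct = config$perturbation_pct,
        baseline_total = config$baseline_total,
        outlier_rate = config$outlier_rate, seed = NULL,
        id = id, group = g, covariate = cov)
      truth[[k]] <- data.frame(participant_id = id, group = g, t(p),
                               covariate = cov, stringsAsFactors = FALSE)
    }
  }
  list(participants = participants, truth = do.call(rbind, truth))
}
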