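#' Forward simulation of the candidate learning models
#'
#' Deterministic stride-by-stride simulation of the three state-space
#' models of split-belt adaptation over the Adaptation and De-adaptation
#' phases of a schedule (Baseline is not modelled). The motor output `x`
#' is on the Adaptation Index scale: the perturbation signal is 1 while
#' the belts are split and 0 once they are tied again, all states start
#' at 0, and every state corrects the shared implicit error
#' `error[s] = perturbation[s] - ximplicit[s]`.
#'
#' `simulateVC()` runs the voluntary-correction model: fast and slow
#' implicit states
#' `xfast[s+1] = Afast*xfast[s] + Bfast*error[s]`,
#' `xslow[s+1] = Aslow*xslow[s] + Bslow*error[s]`,
#' plus a memoryless explicit state that is only expressed while the
#' visual feedback is on, `xexplicit[s+1] = Bexplicit*error[s]`, and is 0
#' otherwise (including the very first stride, which has no prior error).
#' The output is `x = xexplicit + xfast + xslow`.
#'
#' `simulateDualRate()` is the same with no explicit state;
#' `simulateSingleRate()` collapses the implicit pair to one state with
#' `x[s+1] = A*x[s] + B*error[s]`, `error[s] = perturbation[s] - x[s]`.
#'
#' @param params A [vcParams()], [dualRateParams()] or
#'   [singleRateParams()] object (a plain named vector is accepted).
#' @param schedule A [phaseSchedule()].
#' @return A `model_trajectory` data frame with one row per simulated
#'   stride and columns `phase`, `stride` (1-based within phase), `x`,
#'   `ximplicit`, `xfast`, `xslow`, `xexplicit`, `error`,
#'   `perturbation_signal`, `feedback_on`.
#' @examples
#' traj <- simulateVC(vcParams(Bexplicit = 0.2), phaseSchedule())
#' head(traj, 3)
#' @export
simulateVC <- function(params, schedule = phaseSchedule()) {
  p <- asParamVector(params, c("Afast", "Bfast", "Aslow", "Bslow", "Bexplicit"))
  g <- modelGrid(schedule)
  m <- cpp_simulate_vc(g$pert, g$fb, p[["Afast"]], p[["Bfast"]],
                       p[["Aslow"]], p[["Bslow"]], p[["Bexplicit"]])
  makeTrajectory(g, x = m[, 5], ximplicit = m[, 4], xfast = m[, 1],
                 xslow = m[, 2], xexplicit = m[, 3], error = m[, 6])
}

#' @rdname simulateVC
#' @export
simulateDualRate <- function(params, schedule = phaseSchedule()) {
  p <- asParamVector(params, c("Afast", "Bfast", "Aslow", "Bslow"))
  g <- modelGrid(schedule)
  m <- cpp_simulate_vc(g$pert, g$fb, p[["Afast"]], p[["Bfast"]],
                       p[["Aslow"]], p[["Bslow"]], 0)
  makeTrajectory(g, x = m[, 5], ximplicit = m[, 4], xfast = m[, 1],
                 xslow = m[, 2], xexplicit = m[, 3], error = m[, 6])
}

#' @rdname simulateVC
#' @export
simulateSingleRate <- function(params, schedule = phaseSchedule()) {
  p <- asParamVector(params, c("A", "B"))
  g <- modelGrid(schedule)
  m <- cpp_simulate_single(g$pert, p[["A"]], p[["B"]])
  makeTrajectory(g, x = m[, 1], ximplicit = m[, 1],
                 xfast = rep(NA_real_, length(g$pert)),
                 xslow = rep(NA_real_, length(g$pert)),
                 xexplicit = rep(0, length(g$pert)), error = m[, 2])
}

asParamVector <- function(params, expected) {
  p <- unclass(params)
  if (!is.numeric(p) || !all(expected %in% names(p)))
    stop("params must provide: ", paste(expected, collapse = ", "))
  if (any(!is.finite(p[expected]))) stop("parameters must be finite")
  p[expected]
}

makeTrajectory <- function(g, ...) {
  out <- data.frame(phase = g$phase, stride = g$stride, ...,
                    perturbation_signal = g$pert, feedback_on = g$fb,
                    stringsAsFactors = FALSE)
  class(out) <- c("model_trajectory", "data.frame")
  out
}

#' Model output on the stride grid of a raw perturbation/feedback signal
#'
#' Low-level variant of the simulators used by the fitter: simulates a
#' model directly on explicit `pert`/`fb` vectors and returns only the
#' output `x`.
#'
#' @param model One of `"single"`, `"dual"`, `"vc"`.
#' @param theta Numeric parameter vector in the model's canonical order
#'   (`c(A, B)`, `c(Afast, Bfast, Aslow, Bslow)` or that plus `Bexplicit`).
#' @param pert Numeric perturbation signal (1 split, 0 tied) per stride.
#' @param fb Logical feedback flag per stride.
#' @return Numeric vector of model output `x`, one value per stride.
#' @keywords internal
#' @export
modelOutput <- function(model, theta, pert, fb = rep(FALSE, length(pert))) {
  switch(model,
    single = cpp_simulate_single(pert, theta[1], theta[2])[, 1],
    dual = cpp_simulate_vc(pert, fb, theta[1], theta[2], theta[3],
                           theta[4], 0)[, 5],
    vc = cpp_simulate_vc(pert, fb, theta[1], theta[2], theta[3],
                         theta[4], theta[5])[, 5],
    stop("unknown model: ", model))
}
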