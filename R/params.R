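#' Learning-model parameter sets
#'
#' Constructors for the parameter vectors of the three candidate
#' stride-by-stride learning models. All rates are dimensionless,
#' per-stride proportions constrained to \[0, 1\].
#'
#' * `vcParams()` — the five-parameter voluntary-correction model:
#'   fast/slow implicit states with retention rates `Afast`, `Aslow` and
#'   learning rates `Bfast`, `Bslow`, plus a feedback-gated explicit
#'   learning rate `Bexplicit`.
#' * `dualRateParams()` — the nested four-parameter implicit-only model.
#' * `singleRateParams()` — a single state with retention `A` and
#'   learning rate `B`.
#'
#' The implicit parameters obey the identifiability constraints used when
#' fitting: `Bfast >= 5 * Bslow` and `Aslow >= Afast` (the fast process
#' learns and forgets faster than the slow one). Constructors check bounds
#' always and the ordering constraints only when `check_order = TRUE`
#' (generative draws may be projected back instead, see
#' [simulateCohort()]).
#'
#' @param Afast,Aslow Retention rates of the fast and slow implicit states.
#' @param Bfast,Bslow Learning rates of the fast and slow implicit states.
#' @param Bexplicit Explicit (voluntary-correction) learning rate.
#' @param A,B Retention and learning rate of the single-rate model.
#' @param check_order Enforce `Bfast >= 5*Bslow` and `Aslow >= Afast`?
#' @return A named numeric vector with class `vc_params`,
#'   `dual_rate_params` or `single_rate_params`.
#' @examples
#' vcParams(0.92, 0.03, 0.996, 0.004, Bexplicit = 0.2)
#' @export
vcParams <- function(Afast = 0.92, Bfast = 0.03, Aslow = 0.996,
                     Bslow = 0.004, Bexplicit = 0.2, check_order = TRUE) {
  p <- c(Afast = Afast, Bfast = Bfast, Aslow = Aslow, Bslow = Bslow,
         Bexplicit = Bexplicit)
  checkRates(p, check_order)
  structure(p, class = "vc_params")
}

#' @rdname vcParams
#' @export
dualRateParams <- function(Afast = 0.92, Bfast = 0.03, Aslow = 0.996,
                           Bslow = 0.004, check_order = TRUE) {
  p <- c(Afast = Afast, Bfast = Bfast, Aslow = Aslow, Bslow = Bslow)
  checkRates(p, check_order)
  structure(p, class = "dual_rate_params")
}

#' @rdname vcParams
#' @export
singleRateParams <- function(A = 0.96, B = 0.017) {
  p <- c(A = A, B = B)
  checkRates(p, check_order = FALSE)
  structure(p, class = "single_rate_params")
}

checkRates <- function(p, check_order) {
  if (any(!is.finite(p))) stop("parameters must be finite")
  if (any(p < 0 | p > 1)) stop("all rates must lie in [0, 1]")
  if (check_order && all(c("Afast", "Aslow") %in% names(p))) {
    if (p[["Bfast"]] < 5 * p[["Bslow"]] - 1e-12)
      stop("Bfast must be at least 5 times Bslow")
    if (p[["Aslow"]] < p[["Afast"]] - 1e-12)
      stop("Aslow must be at least Afast")
  }
  invisible(p)
}
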