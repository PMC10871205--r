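#' Step length asymmetry
#'
#' Normalised difference between the fast-limb and slow-limb step lengths,
#' in percent: `100 * (fast - slow) / (fast + slow)`. 0 is perfect
#' symmetry; values further from 0 are more asymmetric.
#'
#' @param fast_step,slow_step Step lengths (cm), recycled as usual.
#' @return Numeric vector of asymmetries (%).
#' @examples
#' stepLengthAsymmetry(60, 40) # 20
#' @export
stepLengthAsymmetry <- function(fast_step, slow_step) {
  tot <- fast_step + slow_step
  if (any(!is.na(tot) & tot == 0)) stop("fast + slow step length must be non-zero")
  100 * (fast_step - slow_step) / tot
}

#' Build a step-length-asymmetry series from raw stride data
#'
#' Converts a per-stride step-length table (as produced by
#' [simulateParticipant()] or read with [readStrideCSV()]) into an
#' `asymmetry_series`: one row per stride with the asymmetry in percent
#' and a `retained` flag that downstream cleaning steps switch off.
#'
#' @param strides A `stride_series` data frame with columns `phase`,
#'   `stride`, `fast_step_cm`, `slow_step_cm` (extra columns are kept as
#'   attributes where relevant).
#' @return An `asymmetry_series` data frame with columns `phase`,
#'   `stride`, `sla`, `retained` and attributes `participant_id`, `group`,
#'   `baseline_corrected` (FALSE), `removed_fraction` (0).
#' @export
asAsymmetrySeries <- function(strides) {
  stopifnot(all(c("phase", "stride", "fast_step_cm", "slow_step_cm")
                %in% names(strides)))
  out <- data.frame(phase = strides$phase, stride = strides$stride,
                    sla = stepLengthAsymmetry(strides$fast_step_cm,
                                              strides$slow_step_cm),
                    retained = TRUE,
                    feedback_on = if ("feedback_on" %in% names(strides))
                      as.logical(strides$feedback_on) else FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "participant_id") <- attr(strides, "participant_id") %||%
    (if ("participant_id" %in% names(strides)) strides$participant_id[1] else NA)
  attr(out, "group") <- attr(strides, "group") %||%
    (if ("group" %in% names(strides)) strides$group[1] else NA)
  attr(out, "baseline_corrected") <- FALSE
  attr(out, "removed_fraction") <- 0
  attr(out, "outlier_fraction") <- 0
  class(out) <- c("asymmetry_series", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Baseline-correct a step-length-asymmetry series
#'
#' Subtracts the participant's mean Baseline-phase asymmetry (over
#' retained Baseline strides) from every stride, so the Baseline mean of
#' the corrected series is 0. Idempotent once applied.
#'
#' @param series An `asymmetry_series`.
#' @return The corrected series, with attribute `baseline_corrected = TRUE`.
#' @export
baselineCorrect <- function(series) {
  b <- series$retained & series$phase == "Baseline"
  if (!any(b)) stop("no retained Baseline strides to correct against")
  series$sla <- series$sla - mean(series$sla[b])
  attr(series, "baseline_corrected") <- TRUE
  series
}

#' Flag outlier strides with a 3x IQR fence
#'
#' Marks as not retained any stride whose asymmetry falls outside
#' `[Q1 - 3*IQR, Q3 + 3*IQR]`, with quartiles computed over the
#' participant's full retained series. Strides inside the fence are never
#' touched. A zero IQR (heavily tied series) is degenerate: the fence
#' collapses onto the quartiles and a warning is issued.
#'
#' @param series An `asymmetry_series` with at least 4 strides.
#' @return The series with outliers flagged and the attributes
#'   `removed_fraction` / `outlier_fraction` (percent of strides) updated.
#' @export
removeOutliers <- function(series) {
  if (nrow(series) < 4L) stop("need at least 4 strides to estimate the fence")
  x <- series$sla[series$retained]
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, na.rm = TRUE)
  iqr <- q[2] - q[1]
  if (iqr == 0) warning("IQR is zero; outlier fence is degenerate")
  out <- series$retained & (series$sla < q[1] - 3 * iqr |
                            series$sla > q[2] + 3 * iqr)
  series$retained[out] <- FALSE
  attr(series, "outlier_fraction") <- 100 * sum(out) / nrow(series)
  attr(series, "removed_fraction") <- 100 * mean(!series$retained)
  series
}

#' Drop the first stride of every phase
#'
#' The first stride of each phase is contaminated by treadmill belt
#' acceleration and is excluded from all analyses.
#'
#' @param series An `asymmetry_series`; every phase must have at least 2
#'   strides.
#' @return The series with stride 1 of each phase marked not retained.
#' @export
dropFirstStrides <- function(series) {
  n_per <- table(series$phase)
  if (any(n_per < 2L)) stop("every phase needs at least 2 strides")
  series$retained[series$stride == 1L] <- FALSE
  attr(series, "removed_fraction") <- 100 * mean(!series$retained)
  series
}

# Shared Adaptation Index normaliser:
# condition = 1 while belts are split (Adaptation), 0 when tied; the
# per-phase perturbation is the min (Adaptation) or max (De-adaptation)
# asymmetry over the first 10 retained strides of that phase;
# AI = (sla - condition*perturbation) / |perturbation|.
aiNormalise <- function(phase, stride, sla, retained) {
  pertOf <- function(ph, f) {
    i <- which(phase == ph & retained)
    if (length(i) == 0L) stop("no retained strides in ", ph, " phase")
    i10 <- i[seq_len(min(10L, length(i)))]
    if (length(i10) < 10L)
      warning("fewer than 10 retained strides in ", ph,
              "; perturbation uses ", length(i10))
    f(sla[i10])
  }
  pA <- pertOf("Adaptation", min)
  pD <- pertOf("Deadaptation", max)
  if (pA == 0 || pD == 0)
    stop("perturbation is zero; Adaptation Index is undefined")
  ai <- rep(NA_real_, length(sla))
  cond <- as.numeric(phase == "Adaptation")
  iA <- phase == "Adaptation"
  iD <- phase == "Deadaptation"
  ai[iA] <- (sla[iA] - pA) / abs(pA)
  ai[iD] <- sla[iD] / abs(pD)
  list(ai = ai, condition = cond,
       perturbation = c(Adaptation = pA, Deadaptation = pD))
}

#' Compute the Adaptation Index series
#'
#' Rescales a cleaned, baseline-corrected asymmetry series so that during
#' Adaptation 0 is the maximal perturbation (the minimum asymmetry over
#' the first 10 retained Adaptation strides) and 1 is full correction,
#' while during De-adaptation 1 is the peak aftereffect (the maximum over
#' the first 10 retained De-adaptation strides) and 0 is a washed-out
#' pattern. Baseline strides get `AI = NA`.
#'
#' @param series A baseline-corrected `asymmetry_series` containing
#'   Adaptation and De-adaptation strides.
#' @return An `ai_series` data frame with columns `phase`, `stride`,
#'   `sla`, `retained`, `condition`, `ai`; attributes `perturbation`
#'   (named vector, % asymmetry per phase), plus those of the input.
#' @export
adaptationIndex <- function(series) {
  if (!isTRUE(attr(series, "baseline_corrected")))
    stop("series must be baseline-corrected first")
  if (!all(c("Adaptation", "Deadaptation") %in% series$phase))
    stop("Adaptation and Deadaptation phases are both required")
  norm <- aiNormalise(series$phase, series$stride, series$sla, series$retained)
  out <- series
  out$condition <- norm$condition
  out$ai <- norm$ai
  attr(out, "perturbation") <- norm$perturbation
  class(out) <- c("ai_series", class(series))
  out
}

#' Full preprocessing pipeline
#'
#' Applies, in order: asymmetry computation, baseline correction, 3x IQR
#' outlier flagging, first-stride removal, and Adaptation Index
#' normalisation.
#'
#' @param strides A `stride_series` data frame (see [asAsymmetrySeries()]).
#' @return An `ai_series` (see [adaptationIndex()]).
#' @examples
#' p <- simulateParticipant(vcParams(), noise_sd = 0.05, seed = 1)
#' ai <- preprocess(p)
#' attr(ai, "perturbation")
#' @export
preprocess <- function(strides) {
  adaptationIndex(dropFirstStrides(removeOutliers(baselineCorrect(
    asAsymmetrySeries(strides)))))
}

#' Wrap a model-scale AI vector as an Adaptation Index series
#'
#' Builds an `ai_series` directly from an Adaptation Index vector defined
#' on the Adaptation + De-adaptation stride grid of a schedule — the form
#' in which model-recovery simulations and group-average learning curves
#' live. All strides are retained; `NA` marks removed strides.
#'
#' @param ai Numeric vector, one value per Adaptation and De-adaptation
#'   stride of `schedule`.
#' @param schedule A [phaseSchedule()].
#' @param participant_id,group Labels attached as attributes.
#' @return An `ai_series` (no Baseline rows; `sla` is NA).
#' @export
asAISeries <- function(ai, schedule = phaseSchedule(),
                       participant_id = NA_character_,
                       group = NA_character_) {
  g <- modelGrid(schedule)
  if (length(ai) != length(g$pert))
    stop("ai length must match the Adaptation+Deadaptation grid")
  out <- data.frame(phase = g$phase, stride = g$stride, sla = NA_real_,
                    retained = !is.na(ai), feedback_on = g$fb,
                    condition = g$pert, ai = as.numeric(ai),
                    stringsAsFactors = FALSE)
  attr(out, "participant_id") <- participant_id
  attr(out, "group") <- group
  attr(out, "baseline_corrected") <- TRUE
  class(out) <- c("ai_series", "asymmetry_series", "data.frame")
  out
}
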