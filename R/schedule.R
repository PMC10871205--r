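#' Experimental phase schedule
#'
#' Defines the stride counts of the three walking phases and the window of
#' Adaptation strides during which the step-length visual feedback is shown.
#' The canonical protocol is Baseline (belts tied), Adaptation (belts split
#' 2:1, feedback on for the first 40 strides), then De-adaptation (belts
#' tied again), in that order.
#'
#' @param baseline,adaptation,deadaptation Number of strides in each phase.
#' @param feedback_window Integer vector of length 2: first and last stride
#'   of the Adaptation phase (1-based, inclusive) with feedback on.
#' @return An object of class `phase_schedule`: a list with elements
#'   `phases` (named stride counts) and `feedback_window`.
#' @examples
#' sched <- phaseSchedule()
#' sched
#' @export
phaseSchedule <- function(baseline = 150L, adaptation = 450L,
                           deadaptation = 450L, feedback_window = c(1L, 40L)) {
  n <- c(Baseline = as.integer(baseline), Adaptation = as.integer(adaptation),
         Deadaptation = as.integer(deadaptation))
  if (any(is.na(n)) || any(n < 1L))
    stop("all phases must have at least one stride")
  fw <- as.integer(feedback_window)
  if (length(fw) != 2L || any(is.na(fw)) || fw[1] < 1L || fw[2] < fw[1] ||
      fw[2] > n[["Adaptation"]])
    stop("feedback_window must lie entirely within the Adaptation phase")
  structure(list(phases = n, feedback_window = fw), class = "phase_schedule")
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat("Phase schedule:",
      paste(names(x$phases), x$phases, sep = "=", collapse = ", "),
      sprintf("| feedback on Adaptation strides %d-%d\n",
              x$feedback_window[1], x$feedback_window[2]))
  invisible(x)
}

# Perturbation and feedback signals on the modelled stride grid
# (Adaptation + De-adaptation only; Baseline is not modelled).
modelGrid <- function(schedule) {
  stopifnot(inherits(schedule, "phase_schedule"))
  nA <- schedule$phases[["Adaptation"]]
  nD <- schedule$phases[["Deadaptation"]]
  pert <- c(rep(1, nA), rep(0, nD))
  fb <- rep(FALSE, nA + nD)
  fb[schedule$feedback_window[1]:schedule$feedback_window[2]] <- TRUE
  list(pert = pert, fb = fb,
       phase = rep(c("Adaptation", "Deadaptation"), c(nA, nD)),
       stride = c(seq_len(nA), seq_len(nD)))
}
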