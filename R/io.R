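#' Read and write stride-level CSV files
#'
#' A cohort is stored as one CSV per participant with columns
#' `participant_id`, `group`, `phase`, `stride`, `fast_step_cm`,
#' `slow_step_cm`, `feedback_on`, plus a `manifest.csv` holding the
#' true generating parameters and covariates (for synthetic cohorts).
#'
#' @param cohort A list as returned by [simulateCohort()].
#' @param dir Directory to write into (created if missing).
#' @return `writeCohortCSV()` returns the directory invisibly;
#'   `readStrideCSV()` a `stride_series`; `readCohortCSV()` a list with
#'   `participants` and `truth` (NULL when no manifest is present).
#' @export
writeCohortCSV <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in cohort$participants)
    utils::write.csv(as.data.frame(p),
                     file.path(dir, paste0(p$participant_id[1], ".csv")),
                     row.names = FALSE)
  if (!is.null(cohort$truth))
    utils::write.csv(cohort$truth, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname writeCohortCSV
#' @param path Path of one participant CSV.
#' @export
readStrideCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "group", "phase", "stride",
            "fast_step_cm", "slow_step_cm", "feedback_on")
  if (!all(need %in% names(d)))
    stop("missing columns: ", paste(setdiff(need, names(d)), collapse = ", "))
  d$feedback_on <- as.logical(d$feedback_on)
  attr(d, "participant_id") <- d$participant_id[1]
  attr(d, "group") <- d$group[1]
  class(d) <- c("stride_series", "data.frame")
  d
}

#' @rdname writeCohortCSV
#' @export
readCohortCSV <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- files[basename(files) == "manifest.csv"]
  files <- setdiff(files, manifest)
  participants <- lapply(files, readStrideCSV)
  names(participants) <- vapply(participants,
                                function(p) p$participant_id[1], "")
  truth <- if (length(manifest))
    utils::read.csv(manifest, stringsAsFactors = FALSE) else NULL
  list(participants = participants, truth = truth)
}

#' Write a processed Adaptation Index series as tidy CSV
#'
#' @param ai An `ai_series` from [preprocess()] / [adaptationIndex()].
#' @param path Output file.
#' @export
writeAICSV <- function(ai, path) {
  d <- as.data.frame(ai)
  pert <- attr(ai, "perturbation")
  d$perturbation <- ifelse(d$phase == "Adaptation", pert[["Adaptation"]],
                           ifelse(d$phase == "Deadaptation",
                                  pert[["Deadaptation"]], NA_real_))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
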