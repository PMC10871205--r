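#' Behavioural timepoint means
#'
#' Averages the Adaptation Index over the four 5-stride windows used for
#' the behavioural analysis:
#'
#' * Feedback On — the last 5 strides of the feedback window
#'   (raw Adaptation strides 36-40 under the default schedule);
#' * Feedback Off — the 5 strides immediately after (41-45);
#' * End Adaptation — the last 5 Adaptation strides;
#' * Implicit Aftereffect — the first 5 De-adaptation strides.
#'
#' Feedback On reflects implicit adaptation plus explicit correction,
#' Feedback Off implicit adaptation alone, so their difference
#' (`explicit_magnitude`) quantifies explicit learning. Windows are
#' defined on raw stride indices and intersected with retained strides
#' (removed strides shrink a window; a fully removed window yields NA
#' with a warning).
#'
#' @param ai An `ai_series` from [preprocess()].
#' @param schedule The [phaseSchedule()] the series was collected under.
#' @return A one-row `timepoint_summary` data frame: `participant_id`,
#'   `group`, the four window means, `explicit_magnitude`
#'   (= feedback_on_mean - feedback_off_mean), and `n_*` columns with the
#'   retained strides per window.
#' @export
timepointMeans <- function(ai, schedule = phaseSchedule()) {
  stopifnot(inherits(ai, "ai_series"))
  fw <- schedule$feedback_window
  nA <- schedule$phases[["Adaptation"]]
  wins <- list(
    feedback_on = list("Adaptation", (fw[2] - 4L):fw[2]),
    feedback_off = list("Adaptation", (fw[2] + 1L):(fw[2] + 5L)),
    end_adaptation = list("Adaptation", (nA - 4L):nA),
    implicit_aftereffect = list("Deadaptation", 1:5))
  vals <- lapply(names(wins), function(w) {
    ph <- wins[[w]][[1]]; idx <- wins[[w]][[2]]
    sel <- ai$phase == ph & ai$stride %in% idx & ai$retained & is.finite(ai$ai)
    if (!any(sel)) {
      warning("window '", w, "' fully removed by cleaning for participant ",
              attr(ai, "participant_id"))
      return(c(NA_real_, 0))
    }
    c(mean(ai$ai[sel]), sum(sel))
  })
  m <- vapply(vals, `[`, numeric(2), 1:2)
  out <- data.frame(
    participant_id = as.character(attr(ai, "participant_id") %||% NA),
    group = as.character(attr(ai, "group") %||% NA),
    feedback_on_mean = m[1, 1], feedback_off_mean = m[1, 2],
    end_adaptation_mean = m[1, 3], implicit_aftereffect_mean = m[1, 4],
    explicit_magnitude = m[1, 1] - m[1, 2],
    n_feedback_on = m[2, 1], n_feedback_off = m[2, 2],
    n_end_adaptation = m[2, 3], n_implicit_aftereffect = m[2, 4],
    stringsAsFactors = FALSE)
  class(out) <- c("timepoint_summary", "data.frame")
  out
}

#' Cohort-level timepoint summary
#'
#' Stacks per-participant [timepointMeans()] rows, returning both the
#' per-group descriptive statistics and the tidy long table consumed by
#' [fitGroupTimeModel()].
#'
#' @param summaries List (or rbind-able data frame) of
#'   `timepoint_summary` rows.
#' @return List with `long` (participant, group, timepoint, value) and
#'   `stats` (group x timepoint mean and SD).
#' @export
groupSummary <- function(summaries) {
  tab <- if (is.data.frame(summaries)) summaries
         else do.call(rbind, summaries)
  if (nrow(tab) < 1L || any(!nzchar(tab$group)) || anyNA(tab$group))
    stop("every participant needs a group label")
  tp <- c("feedback_on_mean", "feedback_off_mean", "end_adaptation_mean",
          "implicit_aftereffect_mean", "explicit_magnitude")
  labels <- c("FeedbackOn", "FeedbackOff", "EndAdaptation",
              "ImplicitAftereffect", "ExplicitMagnitude")
  long <- do.call(rbind, lapply(seq_along(tp), function(i)
    data.frame(participant = tab$participant_id, group = tab$group,
               timepoint = labels[i], value = tab[[tp[i]]],
               stringsAsFactors = FALSE)))
  stats_tab <- do.call(rbind, lapply(split(long, long[c("group", "timepoint")]),
    function(d) data.frame(group = d$group[1], timepoint = d$timepoint[1],
                           mean = mean(d$value, na.rm = TRUE),
                           sd = stats::sd(d$value), n = nrow(d),
                           stringsAsFactors = FALSE)))
  rownames(stats_tab) <- NULL
  list(long = long, stats = stats_tab)
}
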