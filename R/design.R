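#' Association-learning task design
#'
#' Parameters of the feedback-based association learning task: faces are
#' learned over repeated presentations, each trial running through recall,
#' confidence selection, feedback and (re-)encoding epochs separated by a
#' jittered inter-trial fixation. Defaults reproduce the study task: 5 runs of
#' 8 new faces presented 4 times each (160 trials), same-face gaps between 2
#' and 15 trials, ITI jittered uniformly on 2.5-6 s, TR 2 s.
#'
#' The recall and confidence phases are self-paced in the real task; fixed
#' stand-in durations are used here (recall 2 s covering face onset plus the
#' gabor choice, confidence 1 s). Feedback lasts 0.8 s after a 0.2 s delay and
#' encoding 1.5 s.
#'
#' @param n_runs number of independent runs.
#' @param faces_per_run new faces introduced per run.
#' @param presentations_per_face presentations of each face within its run.
#' @param iti_range length-2 numeric, uniform jitter bounds for the
#'   inter-trial fixation (seconds).
#' @param event_durations named numeric, seconds per epoch
#'   (`recall`, `confidence`, `feedback`, `encoding`).
#' @param pre_feedback_delay seconds between confidence offset and feedback.
#' @param min_gap,max_gap allowed range (in trials) between consecutive
#'   presentations of the same face.
#' @param tr repetition time of the simulated scan (seconds).
#' @return an object of class `task_design`.
#' @export
task_design <- function(n_runs = 5, faces_per_run = 8, presentations_per_face = 4,
                        iti_range = c(2.5, 6),
                        event_durations = c(recall = 2.0, confidence = 1.0,
                                            feedback = 0.8, encoding = 1.5),
                        pre_feedback_delay = 0.2,
                        min_gap = 2, max_gap = 15, tr = 2.0) {
  stopifnot(n_runs >= 1, faces_per_run >= 1, presentations_per_face >= 1,
            length(iti_range) == 2, iti_range[1] <= iti_range[2],
            iti_range[1] >= 0, min_gap >= 1, max_gap >= min_gap, tr > 0,
            all(c("recall", "confidence", "feedback", "encoding") %in%
                  names(event_durations)),
            all(event_durations > 0))
  structure(list(n_runs = n_runs, faces_per_run = faces_per_run,
                 presentations_per_face = presentations_per_face,
                 iti_range = iti_range,
                 event_durations = event_durations,
                 pre_feedback_delay = pre_feedback_delay,
                 min_gap = min_gap, max_gap = max_gap, tr = tr),
            class = "task_design")
}

#' 1-back localizer task design
#'
#' Defaults reproduce the study localizer: 5 runs, each showing 2 new faces
#' and 2 new houses 4 times (16 trials per run, 80 in total), with direct
#' repetitions of the preceding stimulus/gabor pair on 2 of 16 trials.
#' Stimulus duration 1.5 s; ITI jitter as in the association task.
#'
#' @param n_runs number of runs.
#' @param stimuli_per_category new faces (and houses) per run.
#' @param presentations_per_stimulus presentations of each stimulus per run.
#' @param repetition_rate fraction of trials per run that directly repeat the
#'   preceding stimulus pair.
#' @param stimulus_duration seconds of stimulus presentation.
#' @param iti_range,tr as in [task_design()].
#' @return an object of class `localizer_design`.
#' @export
localizer_design <- function(n_runs = 5, stimuli_per_category = 2,
                             presentations_per_stimulus = 4,
                             repetition_rate = 2 / 16,
                             stimulus_duration = 1.5,
                             iti_range = c(2.5, 6), tr = 2.0) {
  stopifnot(n_runs >= 1, stimuli_per_category >= 1,
            presentations_per_stimulus >= 1,
            repetition_rate >= 0, repetition_rate < 1,
            stimulus_duration > 0, length(iti_range) == 2,
            iti_range[1] <= iti_range[2], tr > 0)
  trials_per_run <- 2 * stimuli_per_category * presentations_per_stimulus
  n_rep <- round(repetition_rate * trials_per_run)
  structure(list(n_runs = n_runs, stimuli_per_category = stimuli_per_category,
                 presentations_per_stimulus = presentations_per_stimulus,
                 repetition_rate = repetition_rate,
                 trials_per_run = trials_per_run,
                 repetitions_per_run = n_rep,
                 stimulus_duration = stimulus_duration,
                 iti_range = iti_range, tr = tr),
            class = "localizer_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat("Association task design:", x$n_runs, "runs x", x$faces_per_run,
      "faces x", x$presentations_per_face, "presentations =",
      x$n_runs * x$faces_per_run * x$presentations_per_face, "trials\n")
  cat("  same-face gap [", x$min_gap, ",", x$max_gap, "] trials; ITI U(",
      x$iti_range[1], ",", x$iti_range[2], ") s; TR", x$tr, "s\n")
  invisible(x)
}

#' @export
print.localizer_design <- function(x, ...) {
  cat("Localizer design:", x$n_runs, "runs x", x$trials_per_run,
      "trials (", x$repetitions_per_run, "direct repetitions per run )\n")
  invisible(x)
}
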