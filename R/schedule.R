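# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so schedule generation never perturbs other
# simulations.
with_seed <- function(seed, code) {
  force(seed) # a seed drawn from the caller's stream must advance it
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  code
}

# Sequence `faces_per_run` faces x `presentations` subject to the same-face
# gap constraint, by constrained sequential sampling with bounded restarts.
sequence_run_faces <- function(n_faces, presentations, min_gap, max_gap,
                               max_tries = 2000L) {
  n_trials <- n_faces * presentations
  for (try in seq_len(max_tries)) {
    remaining <- rep(presentations, n_faces)
    last_pos <- rep(NA_integer_, n_faces)
    seq_out <- integer(n_trials)
    ok <- TRUE
    for (i in seq_len(n_trials)) {
      active <- which(remaining > 0L)
      gap_ok <- active[is.na(last_pos[active]) |
                         (i - last_pos[active]) >= min_gap]
      forced <- active[!is.na(last_pos[active]) &
                         (i - last_pos[active]) >= max_gap]
      if (length(forced) > 1L) { ok <- FALSE; break }
      pool <- if (length(forced) == 1L) forced else gap_ok
      if (length(pool) == 0L) { ok <- FALSE; break }
      f <- if (length(pool) == 1L) pool else sample(pool, 1L)
      seq_out[i] <- f
      remaining[f] <- remaining[f] - 1L
      last_pos[f] <- i
    }
    if (ok) return(seq_out)
  }
  stop("schedule-infeasible: could not satisfy same-face gap constraint [",
       min_gap, ", ", max_gap, "] after ", max_tries, " attempts",
       call. = FALSE)
}

#' Generate an association-task trial schedule
#'
#' One row per trial with run, face identity, presentation number and onsets
#' (seconds, run-relative) for the recall, confidence, feedback and encoding
#' epochs plus the jittered fixation intervals. Consecutive presentations of
#' the same face are separated by between `min_gap` and `max_gap` trials. The
#' rehearsal (`iti`) epoch of a trial is the jittered fixation interval that
#' follows its encoding phase.
#'
#' @param design a [task_design()].
#' @param seed integer seed; identical inputs give identical schedules.
#' @return a `data.frame` (class `event_table`) with one row per trial.
#' @export
generate_association_schedule <- function(design, seed = 1L) {
  stopifnot(inherits(design, "task_design"))
  with_seed(seed, {
    runs <- lapply(seq_len(design$n_runs), function(r) {
      faces <- sequence_run_faces(design$faces_per_run,
                                  design$presentations_per_face,
                                  design$min_gap, design$max_gap)
      n <- length(faces)
      pres <- integer(n)
      cnt <- integer(design$faces_per_run)
      for (i in seq_len(n)) {
        cnt[faces[i]] <- cnt[faces[i]] + 1L
        pres[i] <- cnt[faces[i]]
      }
      itis <- stats::runif(n + 1L, design$iti_range[1], design$iti_range[2])
      d <- design$event_durations
      trial_len <- d[["recall"]] + d[["confidence"]] +
        design$pre_feedback_delay + d[["feedback"]] + d[["encoding"]]
      onset_recall <- numeric(n)
      t <- 0
      for (i in seq_len(n)) {
        t <- t + itis[i]
        onset_recall[i] <- t
        t <- t + trial_len
      }
      onset_confidence <- onset_recall + d[["recall"]]
      onset_feedback <- onset_confidence + d[["confidence"]] +
        design$pre_feedback_delay
      onset_encoding <- onset_feedback + d[["feedback"]]
      onset_iti <- onset_encoding + d[["encoding"]]
      data.frame(run = r, trial = seq_len(n),
                 face_id = (r - 1L) * design$faces_per_run + faces,
                 presentation = pres,
                 onset_recall = onset_recall,
                 onset_confidence = onset_confidence,
                 onset_feedback = onset_feedback,
                 onset_encoding = onset_encoding,
                 onset_iti = onset_iti,
                 dur_recall = d[["recall"]],
                 dur_confidence = d[["confidence"]],
                 dur_feedback = d[["feedback"]],
                 dur_encoding = d[["encoding"]],
                 dur_iti = itis[-1L])
    })
    out <- do.call(rbind, runs)
    rownames(out) <- NULL
    class(out) <- c("event_table", "data.frame")
    out
  })
}

#' Generate a 1-back localizer schedule
#'
#' Each run presents `stimuli_per_category` new faces and houses
#' `presentations_per_stimulus` times each, with exactly
#' `repetitions_per_run` trials that directly repeat the preceding
#' stimulus/gabor pair (flagged `is_repetition`). Categories are balanced
#' within each run.
#'
#' @param design a [localizer_design()].
#' @param seed integer seed.
#' @return a `data.frame` (class `event_table`) with one row per trial.
#' @export
generate_localizer_schedule <- function(design, seed = 1L) {
  stopifnot(inherits(design, "localizer_design"))
  with_seed(seed, {
    runs <- lapply(seq_len(design$n_runs), function(r) {
      n_stim <- 2L * design$stimuli_per_category
      base <- rep(seq_len(n_stim), design$presentations_per_stimulus)
      n <- length(base)
      target_rep <- design$repetitions_per_run
      for (try in seq_len(5000L)) {
        s <- sample(base)
        adj <- which(s[-1L] == s[-n]) + 1L
        runs3 <- any(diff(adj) == 1L)
        if (length(adj) == target_rep && !runs3) break
        if (try == 5000L)
          stop("schedule-infeasible: could not place exactly ", target_rep,
               " direct repetitions per run", call. = FALSE)
      }
      category <- ifelse(s <= design$stimuli_per_category, "face", "house")
      gabor <- sample(8L, n, replace = TRUE)
      is_rep <- seq_len(n) %in% adj
      gabor[is_rep] <- gabor[which(is_rep) - 1L]
      itis <- stats::runif(n, design$iti_range[1], design$iti_range[2])
      onset <- cumsum(itis + design$stimulus_duration) - design$stimulus_duration
      data.frame(run = r, trial = seq_len(n),
                 stimulus_id = (r - 1L) * n_stim + s,
                 category = category,
                 gabor = gabor,
                 is_repetition = is_rep,
                 onset_stimulus = onset,
                 dur_stimulus = design$stimulus_duration)
    })
    out <- do.call(rbind, runs)
    rownames(out) <- NULL
    class(out) <- c("event_table", "data.frame")
    out
  })
}
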