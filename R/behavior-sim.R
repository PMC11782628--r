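#' Behavioral simulation parameters
#'
#' Governs simulated recall accuracy and confidence in the association task.
#' Accuracy follows a logistic learning curve in presentation number: the
#' first presentation is a guess among the 8 gabor orientations
#' (`guess_prob = 1/8`), and each further exposure adds `learning_rate` on the
#' log-odds scale. The default rate (1.7622153) is the analytic solution that
#' makes the design-mean accuracy over four presentations equal 59.35%, the
#' level the task is known to produce. Confidence is high with probability
#' `conf_sensitivity` on correct trials (default 0.8014) and low with
#' probability `conf_specificity` on errors (default 0.7622), the observed
#' meta-memory rates.
#'
#' @param learning_rate per-exposure log-odds increment.
#' @param guess_prob first-presentation success probability.
#' @param conf_sensitivity P(high confidence | correct).
#' @param conf_specificity P(low confidence | error).
#' @param seed integer seed used by [simulate_behavior()].
#' @return an object of class `behavior_params`.
#' @export
behavior_params <- function(learning_rate = 1.7622153, guess_prob = 1 / 8,
                            conf_sensitivity = 0.8014,
                            conf_specificity = 0.7622, seed = 1L) {
  stopifnot(guess_prob >= 0, guess_prob <= 1,
            conf_sensitivity >= 0, conf_sensitivity <= 1,
            conf_specificity >= 0, conf_specificity <= 1)
  structure(list(learning_rate = learning_rate, guess_prob = guess_prob,
                 conf_sensitivity = conf_sensitivity,
                 conf_specificity = conf_specificity,
                 seed = as.integer(seed)),
            class = "behavior_params")
}

#' Simulate recall accuracy and confidence on an association-task schedule
#'
#' Adds `accuracy` (0/1) and `confidence` (`"low"`/`"high"`) columns.
#' Deterministic given `params$seed`.
#'
#' @param schedule an association-task [generate_association_schedule()] table.
#' @param params a [behavior_params()].
#' @return the schedule with `accuracy` and `confidence` columns appended.
#' @export
simulate_behavior <- function(schedule, params = behavior_params()) {
  stopifnot(is.data.frame(schedule), "presentation" %in% names(schedule))
  with_seed(params$seed, {
    p_correct <- stats::plogis(stats::qlogis(params$guess_prob) +
                                 params$learning_rate * (schedule$presentation - 1))
    acc <- as.integer(stats::runif(nrow(schedule)) < p_correct)
    p_high <- ifelse(acc == 1L, params$conf_sensitivity,
                     1 - params$conf_specificity)
    conf <- ifelse(stats::runif(nrow(schedule)) < p_high, "high", "low")
    out <- schedule
    out$accuracy <- acc
    out$confidence <- conf
    class(out) <- c("event_table", "data.frame")
    out
  })
}

#' Simulate button presses on a localizer schedule
#'
#' Presses occur on repetition trials with probability `hit_prob` and on
#' non-repetition trials with probability `fa_prob`; the defaults emulate an
#' attentive participant with optimal performance.
#'
#' @param schedule a [generate_localizer_schedule()] table.
#' @param hit_prob P(press | repetition).
#' @param fa_prob P(press | non-repetition).
#' @param seed integer seed.
#' @return the schedule with a logical `pressed` column appended.
#' @export
simulate_localizer_behavior <- function(schedule, hit_prob = 1, fa_prob = 0,
                                        seed = 1L) {
  stopifnot(is.data.frame(schedule), "is_repetition" %in% names(schedule))
  with_seed(seed, {
    p <- ifelse(schedule$is_repetition, hit_prob, fa_prob)
    out <- schedule
    out$pressed <- stats::runif(nrow(schedule)) < p
    class(out) <- c("event_table", "data.frame")
    out
  })
}

#' Simulate probability-scale face-processing evidence for many participants
#'
#' Lightweight generator operating directly on the calibrated-probability
#' scale of the face-evidence classifier: for each included trial,
#' `face_probability = base + demand_effect * demand + success_effect *
#' success + participant intercept + trial noise`, clipped to [0, 1]. This is
#' the ground-truth model under which the mixed-model linkage
#' ([fit_mixed_model()]) is a correctly specified estimator, so it supports
#' direct parameter-recovery studies without the BOLD forward model.
#'
#' @param n_participants number of simulated participants.
#' @param design association [task_design()] used to build each schedule.
#' @param behavior [behavior_params()] for the simulated accuracies.
#' @param demand_effect probability-scale increment for encoding demand.
#' @param success_effect probability-scale increment for subsequent success.
#' @param base mean face probability of a demand-free, success-free trial.
#' @param participant_sd SD of the participant-level random intercept.
#' @param noise_sd trial-level residual SD.
#' @param epoch epoch label attached to the table.
#' @param seed integer seed.
#' @return an `evidence table` data.frame with columns `participant`, `run`,
#'   `trial_id`, `epoch`, `face_probability`, `predicted_class`, `demand`,
#'   `success`, `transition`.
#' @export
simulate_evidence <- function(n_participants, design = task_design(),
                              behavior = behavior_params(),
                              demand_effect = 0.04, success_effect = 0.015,
                              base = 0.4, participant_sd = 0.05,
                              noise_sd = 0.15, epoch = "encoding", seed = 1L) {
  with_seed(seed, {
    out <- vector("list", n_participants)
    for (p in seq_len(n_participants)) {
      sched <- generate_association_schedule(design,
                                             seed = sample.int(2^30, 1))
      beh <- simulate_behavior(sched, behavior_params(
        learning_rate = behavior$learning_rate,
        guess_prob = behavior$guess_prob,
        conf_sensitivity = behavior$conf_sensitivity,
        conf_specificity = behavior$conf_specificity,
        seed = sample.int(2^30, 1)))
      fac <- code_factors(beh)
      keep <- fac$included
      n <- sum(keep)
      b0 <- stats::rnorm(1, 0, participant_sd)
      prob <- base + b0 + demand_effect * fac$demand[keep] +
        success_effect * fac$success[keep] + stats::rnorm(n, 0, noise_sd)
      prob <- pmin(pmax(prob, 0), 1)
      out[[p]] <- data.frame(
        participant = sprintf("sub-%02d", p),
        run = beh$run[keep],
        trial_id = which(keep),
        epoch = epoch,
        face_probability = prob,
        predicted_class = ifelse(prob >= 0.5, "face", "house"),
        demand = fac$demand[keep],
        success = fac$success[keep],
        transition = fac$transition[keep])
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
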