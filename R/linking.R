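#' Code encoding-demand and subsequent-recall-success trial factors
#'
#' For each trial, the transition is the pair (current recall accuracy, recall
#' accuracy on the next presentation of the same face): `CorrectCorrect`,
#' `CorrectError`, `ErrorCorrect` or `ErrorError`. Encoding demand is 0 for
#' `CorrectCorrect` and 1 for `ErrorError`/`ErrorCorrect`; subsequent recall
#' success is 0 for `ErrorError` and 1 for `ErrorCorrect`/`CorrectCorrect`.
#' `CorrectError` trials and trials without a next presentation (a face's last
#' presentation, or an orphan never re-presented) are excluded.
#'
#' @param trials association event table with `face_id`, `presentation` and
#'   `accuracy` columns.
#' @return data.frame with one row per trial: `transition` (NA when no next
#'   presentation exists), `demand`, `success`, `included`, `reason`.
#' @export
code_factors <- function(trials) {
  stopifnot(all(c("face_id", "presentation", "accuracy") %in% names(trials)))
  n <- nrow(trials)
  next_acc <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    j <- which(trials$face_id == trials$face_id[i] &
                 trials$presentation == trials$presentation[i] + 1L)
    if (length(j) == 1L) next_acc[i] <- trials$accuracy[j]
  }
  cur <- ifelse(trials$accuracy == 1L, "Correct", "Error")
  nxt <- ifelse(next_acc == 1L, "Correct", "Error")
  transition <- ifelse(is.na(next_acc), NA_character_, paste0(cur, nxt))
  demand <- ifelse(transition %in% c("ErrorError", "ErrorCorrect"), 1L,
                   ifelse(transition == "CorrectCorrect", 0L, NA_integer_))
  success <- ifelse(transition %in% c("ErrorCorrect", "CorrectCorrect"), 1L,
                    ifelse(transition == "ErrorError", 0L, NA_integer_))
  included <- !is.na(transition) & transition != "CorrectError"
  reason <- ifelse(is.na(transition), "no next presentation",
                   ifelse(transition == "CorrectError",
                          "CorrectError excluded", ""))
  data.frame(transition = transition, demand = demand, success = success,
             included = included, reason = reason)
}

#' Link face-processing evidence to encoding demand and recall success
#'
#' Fits a linear mixed model of the calibrated face probability on the fixed
#' effects encoding demand and subsequent recall success with a
#' participant-level random intercept (REML), restricted to the included
#' transitions (`ErrorError`, `ErrorCorrect`, `CorrectCorrect`). Inference is
#' Wald: z = estimate / SE with normal p-values and 95% CIs, so coefficients
#' read directly as probability-scale increments. A control variant
#' restricted to `ErrorError`/`ErrorCorrect` trials with success as the sole
#' fixed effect is fit alongside. A singular random-effects fit falls back to
#' an OLS fit with participant-clustered robust standard errors (the
#' downgrade is recorded in the result).
#'
#' @param evidence data.frame with `participant`, `face_probability`,
#'   `demand`, `success` (e.g. from [predict_evidence()] joined to
#'   [code_factors()], or [simulate_evidence()]); rows should already be
#'   restricted to included trials.
#' @param epoch label stored in the result.
#' @return object of class `mixed_model_result` with a `coefficients`
#'   data.frame (term, estimate, se, z, p, ci_lower, ci_upper), the control
#'   fit, `n_trials`, `n_participants`, `method`.
#' @export
fit_mixed_model <- function(evidence, epoch = "encoding") {
  need <- c("participant", "face_probability", "demand", "success")
  stopifnot(all(need %in% names(evidence)))
  if (length(unique(evidence$participant)) < 2)
    stop("need at least 2 participants for the mixed model", call. = FALSE)
  main <- wald_lmm(face_probability ~ demand + success, evidence)
  ctrl_data <- evidence[evidence$demand == 1, , drop = FALSE]
  control <- if (nrow(ctrl_data) > 0 &&
                 length(unique(ctrl_data$success)) > 1 &&
                 length(unique(ctrl_data$participant)) > 1)
    wald_lmm(face_probability ~ success, ctrl_data) else NULL
  structure(list(coefficients = main$coefficients, method = main$method,
                 control = control, epoch = epoch,
                 n_trials = nrow(evidence),
                 n_participants = length(unique(evidence$participant)),
                 model = main$model),
            class = "mixed_model_result")
}

# Random-intercept LMM with Wald inference; participant-clustered robust OLS
# fallback when the random-effects fit is singular or fails.
wald_lmm <- function(formula, data) {
  full_formula <- stats::update(formula, . ~ . + (1 | participant))
  fit <- tryCatch(
    lme4::lmer(full_formula, data = data, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular =
                                             lme4::.makeCC(action = "ignore", tol = 1e-4))),
    error = function(e) NULL)
  if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-4)) {
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    method <- "lmm_reml"
  } else {
    fit <- stats::lm(formula, data = data)
    est <- stats::coef(fit)
    se <- sqrt(diag(sandwich::vcovCL(fit, cluster = data$participant)))
    method <- "ols_cluster_robust"
  }
  z <- est / se
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), z = unname(z),
                      p = 2 * stats::pnorm(-abs(unname(z))),
                      ci_lower = unname(est - 1.96 * se),
                      ci_upper = unname(est + 1.96 * se))
  rownames(coefs) <- NULL
  list(coefficients = coefs, method = method, model = fit)
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("Mixed-model linkage (%s epoch, %d trials, %d participants, %s):\n",
              x$epoch, x$n_trials, x$n_participants, x$method))
  print(x$coefficients, digits = 3)
  if (!is.null(x$control)) {
    cat("Control (demand trials only):\n")
    print(x$control$coefficients, digits = 3)
  }
  invisible(x)
}

#' Regress whole-brain single-trial betaseries on decoded face evidence
#'
#' Per participant, each voxel's betaseries is regressed on the
#' participant-centered face-probability regressor; the per-participant slope
#' maps are then carried to second-level one-sample inference.
#'
#' @param beta_maps list (one element per participant) of trials x voxels
#'   matrices or `vol4d` objects with the trial axis as the 4th dimension.
#' @param evidence list (same order) of per-participant evidence data.frames
#'   with `face_probability` aligned row-for-row with the betaseries trials.
#' @param fwhm smoothing kernel passed to [second_level()] (mm).
#' @param voxel_mm voxel size for smoothing when maps are 3D.
#' @return list: `participant_slopes` (participants x voxels matrix),
#'   `group` (a `group_contrast`), `dropped` (participants with constant
#'   evidence, excluded with a warning).
#' @export
wholebrain_evidence_regression <- function(beta_maps, evidence, fwhm = 0,
                                           voxel_mm = 2.2) {
  stopifnot(length(beta_maps) == length(evidence))
  slopes <- list(); dropped <- integer(0)
  dims <- NULL
  for (p in seq_along(beta_maps)) {
    B <- if (inherits(beta_maps[[p]], "vol4d")) {
      dims <- spatial_dim(beta_maps[[p]])
      as_frame_matrix(beta_maps[[p]])
    } else as.matrix(beta_maps[[p]])
    ev <- evidence[[p]]$face_probability
    stopifnot(length(ev) == nrow(B))
    x <- ev - mean(ev)
    if (stats::sd(x) == 0) {
      warning("participant ", p, " has constant evidence; dropped")
      dropped <- c(dropped, p)
      next
    }
    slopes[[length(slopes) + 1]] <- as.vector(crossprod(x, B)) / sum(x^2)
  }
  if (length(slopes) < 3)
    stop("need at least 3 participants with varying evidence", call. = FALSE)
  S <- do.call(rbind, slopes)
  maps <- lapply(seq_len(nrow(S)), function(i)
    if (is.null(dims)) S[i, ] else array(S[i, ], dims))
  grp <- second_level(maps, fwhm = fwhm, voxel_mm = voxel_mm)
  list(participant_slopes = S, group = grp, dropped = dropped)
}
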