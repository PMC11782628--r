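#' Score learning performance on the association task
#'
#' Computes overall accuracy, per-block (presentation-number) means, a
#' one-sample t-test of per-participant accuracy against chance, and a one-way
#' ANOVA across blocks with Tukey HSD post-hoc comparisons on per-participant
#' block means. With eight response options the chance level is 12.5%.
#'
#' If the table has no `participant` column all trials are treated as one
#' participant and the t-test is computed over trial-level accuracies. A
#' zero-variance accuracy vector yields a capped (finite) t statistic.
#'
#' @param trials event table with `accuracy` and `presentation` columns.
#' @param chance chance-level accuracy (default 1/8).
#' @return a list of class `learning_summary`: `overall_pct`,
#'   `block_means_pct`, `t_test` (estimate, t, p, df, ci), `anova`
#'   (F, df, p), `tukey` (data.frame of pairwise differences).
#' @export
score_learning <- function(trials, chance = 1 / 8) {
  stopifnot(all(c("accuracy", "presentation") %in% names(trials)))
  if (!"participant" %in% names(trials)) trials$participant <- "p1"
  overall <- mean(trials$accuracy)

  per_part <- tapply(trials$accuracy, trials$participant, mean)
  tt <- if (length(per_part) >= 2) capped_t_test(as.numeric(per_part), mu = chance)
        else capped_t_test(as.numeric(trials$accuracy), mu = chance)

  # across participants the ANOVA units are participant block means; with a
  # single participant, trial-level accuracies serve as the observations
  blk <- if (length(per_part) >= 2)
    stats::aggregate(accuracy ~ participant + presentation, data = trials,
                     FUN = mean)
  else trials[, c("participant", "presentation", "accuracy")]
  blk$presentation <- factor(blk$presentation)
  if (any(table(blk$presentation) < 2))
    stop("ANOVA-degenerate: a block has fewer than 2 observations",
         call. = FALSE)
  block_means <- tapply(blk$accuracy, blk$presentation, mean)
  fit <- stats::aov(accuracy ~ presentation, data = blk)
  an <- summary(fit)[[1]]
  tk <- as.data.frame(stats::TukeyHSD(fit)$presentation)
  tk$comparison <- rownames(tk)
  rownames(tk) <- NULL

  structure(list(
    overall_pct = 100 * overall,
    block_means_pct = 100 * block_means,
    chance_pct = 100 * chance,
    t_test = tt,
    anova = list(F = an[["F value"]][1],
                 df = c(an[["Df"]][1], an[["Df"]][2]),
                 p = an[["Pr(>F)"]][1]),
    tukey = tk), class = "learning_summary")
}

#' @export
print.learning_summary <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.2f%% (chance %.1f%%), t(%d) = %.2f, p = %.3g\n",
              x$overall_pct, x$chance_pct, x$t_test$df, x$t_test$t, x$t_test$p))
  cat("Block means (%):", sprintf("%.1f", x$block_means_pct), "\n")
  cat(sprintf("Blocks ANOVA: F(%d,%d) = %.2f, p = %.3g\n",
              x$anova$df[1], x$anova$df[2], x$anova$F, x$anova$p))
  invisible(x)
}

#' Meta-memory sensitivity (d') and bias from confidence reports
#'
#' Signal-detection analysis of confidence as a detector of recall success:
#' the hit rate is P(high confidence | correct) and the false-alarm rate is
#' P(high confidence | error) = 1 - specificity. Rates of exactly 0 or 1 are
#' adjusted by the proportion of one trial (1/n of the relevant count) so
#' their normal quantiles stay finite. Then `d_prime = z(hit) - z(fa)` and the
#' bias is the criterion `c = -(z(hit) + z(fa)) / 2` (labelled as such: a
#' positive value indicates a conservative tendency toward low confidence).
#'
#' @param trials event table with `accuracy` and `confidence` columns.
#' @return list of class `meta_memory`: `d_prime`, `d_bias`, `hit_rate`,
#'   `fa_rate`, `n_correct`, `n_error`.
#' @export
meta_memory <- function(trials) {
  stopifnot(all(c("accuracy", "confidence") %in% names(trials)))
  correct <- trials$accuracy == 1
  n_c <- sum(correct); n_e <- sum(!correct)
  if (n_c == 0 || n_e == 0)
    stop("undefined-metric: need at least one correct and one error trial",
         call. = FALSE)
  hit <- mean(trials$confidence[correct] == "high")
  fa <- mean(trials$confidence[!correct] == "high")
  hit <- adjust_rate(hit, n_c)
  fa <- adjust_rate(fa, n_e)
  structure(list(d_prime = stats::qnorm(hit) - stats::qnorm(fa),
                 d_bias = -(stats::qnorm(hit) + stats::qnorm(fa)) / 2,
                 hit_rate = hit, fa_rate = fa,
                 n_correct = n_c, n_error = n_e),
            class = "meta_memory")
}

# One-trial-proportion adjustment for boundary rates; rates already inside
# (0,1) pass through unchanged.
adjust_rate <- function(rate, n) {
  if (rate >= 1) rate <- 1 - 1 / n
  else if (rate <= 0) rate <- 1 / n
  rate
}

#' @export
print.meta_memory <- function(x, ...) {
  cat(sprintf("Meta-memory d' = %.3f, bias c = %.3f (hit %.3f, fa %.3f; %d correct / %d error trials)\n",
              x$d_prime, x$d_bias, x$hit_rate, x$fa_rate, x$n_correct, x$n_error))
  invisible(x)
}

#' Score localizer performance and apply the 2-SD exclusion rule
#'
#' Classifies trials into hits (press on a repetition), misses, correct
#' rejections (no press on a non-repetition) and false alarms. The scalar task
#' performance is the mean of hit rate and correct-rejection rate; a
#' participant is excluded when it falls strictly below the cohort mean minus
#' two cohort SDs.
#'
#' @param trials localizer event table with `is_repetition` and `pressed`.
#' @param cohort_performances numeric vector of performance scalars of all
#'   cohort participants (including this one) used for the exclusion rule;
#'   with fewer than 2 values exclusion is undefined and the participant is
#'   kept with a warning.
#' @return list of class `localizer_performance`: SDT counts, `hit_rate`,
#'   `cr_rate`, `performance`, `excluded`.
#' @export
score_localizer <- function(trials, cohort_performances = NULL) {
  stopifnot(all(c("is_repetition", "pressed") %in% names(trials)))
  rep_t <- trials$is_repetition
  hits <- sum(rep_t & trials$pressed)
  misses <- sum(rep_t & !trials$pressed)
  crs <- sum(!rep_t & !trials$pressed)
  fas <- sum(!rep_t & trials$pressed)
  hit_rate <- if (sum(rep_t) > 0) hits / sum(rep_t) else NA_real_
  cr_rate <- if (sum(!rep_t) > 0) crs / sum(!rep_t) else NA_real_
  perf <- mean(c(hit_rate, cr_rate), na.rm = TRUE)
  excluded <- FALSE
  if (is.null(cohort_performances) || length(cohort_performances) < 2) {
    warning("cohort of size < 2: exclusion undefined, participant kept")
  } else {
    cut <- mean(cohort_performances) - 2 * stats::sd(cohort_performances)
    excluded <- perf < cut
  }
  structure(list(hits = hits, misses = misses, correct_rejections = crs,
                 false_alarms = fas, hit_rate = hit_rate, cr_rate = cr_rate,
                 performance = perf, excluded = excluded),
            class = "localizer_performance")
}

#' @export
print.localizer_performance <- function(x, ...) {
  cat(sprintf("Localizer: %d hits / %d misses / %d CRs / %d FAs; performance %.3f%s\n",
              x$hits, x$misses, x$correct_rejections, x$false_alarms,
              x$performance, if (x$excluded) " [EXCLUDED]" else ""))
  invisible(x)
}
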