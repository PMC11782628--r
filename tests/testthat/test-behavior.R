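test_that("without learning, accuracy stays at the guessing rate", {
  d <- task_design(n_runs = 10, faces_per_run = 8)
  s <- generate_association_schedule(d, seed = 2)
  b <- simulate_behavior(s, behavior_params(learning_rate = 0,
                                            guess_prob = 1 / 8, seed = 4))
  # 320 trials at p = 1/8: 4 SDs of binomial sampling error
  expect_lt(abs(mean(b$accuracy) - 0.125), 4 * sqrt(0.125 * 0.875 / 320))
})

test_that("accuracy increases with presentation under the logistic curve", {
  s <- generate_association_schedule(task_design(), seed = 2)
  acc <- do.call(rbind, lapply(1:40, function(i)
    tapply(simulate_behavior(s, behavior_params(seed = i))$accuracy,
           s$presentation, mean)))
  expect_true(all(diff(colMeans(acc)) > 0))
})

test_that("score_learning reports accuracy, chance test and block ANOVA", {
  s <- generate_association_schedule(task_design(), seed = 2)
  b <- simulate_behavior(s, behavior_params(seed = 4))
  b$accuracy <- 1L
  res <- score_learning(b)
  expect_equal(res$overall_pct, 100)
  expect_gt(res$t_test$t, 0)
  expect_true(is.finite(res$t_test$t))
  expect_equal(res$chance_pct, 12.5)
})

test_that("equal block means give a near-zero ANOVA F and Tukey differences", {
  trials <- expand.grid(participant = sprintf("p%d", 1:6),
                        presentation = 1:4, trial = 1:10)
  trials$accuracy <- rep(c(1, 0), length.out = nrow(trials))
  res <- score_learning(trials)
  expect_lt(res$anova$F, 1e-10)
  expect_true(all(abs(res$tukey$diff) < 1e-10))
})

test_that("the one-sample chance test has a calibrated type-I rate", {
  set.seed(31)
  n_rep <- 400
  rejections <- replicate(n_rep, {
    # a cohort of chance-level participants: per-participant accuracies are
    # binomial at 12.5% over 160 trials
    acc <- stats::rbinom(15, 160, 0.125) / 160
    memtrace:::capped_t_test(acc, mu = 0.125)$p < 0.05
  })
  rate <- mean(rejections)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep) + 0.01)
})

test_that("meta-memory d' matches the closed form with boundary adjustment", {
  trials <- data.frame(accuracy = rep(c(1, 0), each = 10),
                       confidence = rep(c("high", "low"), each = 10))
  mm <- meta_memory(trials)
  expect_equal(mm$hit_rate, 0.9)
  expect_equal(mm$fa_rate, 0.1)
  # independent oracle: invert the normal CDF with a root finder
  z_oracle <- function(p) uniroot(function(x) pnorm(x) - p, c(-10, 10),
                                  tol = 1e-12)$root
  expect_equal(mm$d_prime, z_oracle(0.9) - z_oracle(0.1), tolerance = 1e-8)
  expect_equal(mm$d_bias, -(z_oracle(0.9) + z_oracle(0.1)) / 2,
               tolerance = 1e-8)
})

test_that("symmetric confidence rates give zero d' and bias", {
  trials <- data.frame(accuracy = rep(c(1, 0), each = 4),
                       confidence = rep(c("high", "low"), 4))
  mm <- meta_memory(trials)
  expect_equal(mm$hit_rate, 0.5)
  expect_equal(mm$fa_rate, 0.5)
  expect_equal(mm$d_prime, 0)
  expect_equal(mm$d_bias, 0)
})

test_that("swapping confidence labels negates d'", {
  set.seed(5)
  trials <- data.frame(accuracy = rep(c(1, 0), c(30, 20)),
                       confidence = sample(c("high", "low"), 50, TRUE))
  mm <- meta_memory(trials)
  flipped <- trials
  flipped$confidence <- ifelse(trials$confidence == "high", "low", "high")
  expect_equal(meta_memory(flipped)$d_prime, -mm$d_prime)
})

test_that("d' is monotone in hit and false-alarm rates; adjustment is idempotent", {
  grid <- seq(0.1, 0.9, by = 0.2)
  make <- function(hit, fa) {
    nh <- round(hit * 20); nf <- round(fa * 20)
    data.frame(accuracy = rep(c(1, 0), each = 20),
               confidence = c(rep(c("high", "low"), c(nh, 20 - nh)),
                              rep(c("high", "low"), c(nf, 20 - nf))))
  }
  d_at <- function(hit, fa) meta_memory(make(hit, fa))$d_prime
  for (fa in c(0.3, 0.5)) {
    dvals <- sapply(grid, d_at, fa = fa)
    expect_true(all(diff(dvals) > 0))
  }
  for (hit in c(0.5, 0.7)) {
    dvals <- sapply(grid, function(fa) d_at(hit, fa))
    expect_true(all(diff(dvals) < 0))
  }
  expect_equal(memtrace:::adjust_rate(0.37, 50), 0.37)
  expect_equal(memtrace:::adjust_rate(1, 10), 0.9)
  expect_equal(memtrace:::adjust_rate(0, 10), 0.1)
})

test_that("meta_memory refuses degenerate inputs", {
  all_correct <- data.frame(accuracy = 1, confidence = "high")[rep(1, 5), ]
  expect_error(meta_memory(all_correct), "undefined-metric")
})

test_that("localizer SDT counts partition trials and rates are exact", {
  s <- generate_localizer_schedule(localizer_design(), seed = 2)
  b <- simulate_localizer_behavior(s, hit_prob = 1, fa_prob = 0, seed = 1)
  perf <- score_localizer(b, cohort_performances = c(1, 1, 0.9))
  expect_equal(perf$hits, 10L)
  expect_equal(perf$misses, 0L)
  expect_equal(perf$correct_rejections, 70L)
  expect_equal(perf$false_alarms, 0L)
  expect_equal(perf$hit_rate, 1)
  expect_equal(perf$cr_rate, 1)
  expect_false(perf$excluded)
  expect_equal(perf$hits + perf$misses + perf$correct_rejections +
                 perf$false_alarms, nrow(b))
})

test_that("the 2-SD exclusion rule flags exactly the planted low performer", {
  s <- generate_localizer_schedule(localizer_design(), seed = 2)
  good <- simulate_localizer_behavior(s, hit_prob = 1, fa_prob = 0, seed = 1)
  bad <- simulate_localizer_behavior(s, hit_prob = 0.1, fa_prob = 0.5,
                                     seed = 2)
  perf_of <- function(b) {
    suppressWarnings(score_localizer(b))$performance
  }
  cohort <- c(rep(perf_of(good), 9), perf_of(bad))
  expect_true(score_localizer(bad, cohort)$excluded)
  expect_false(score_localizer(good, cohort)$excluded)
})

test_that("performance exactly at mean minus 2 SD is not excluded", {
  # a homogeneous cohort puts the cutoff exactly at the participant's own
  # performance (SD = 0); the strict inequality keeps the participant
  s <- generate_localizer_schedule(localizer_design(n_runs = 1), seed = 3)
  b <- simulate_localizer_behavior(s, hit_prob = 1, fa_prob = 0, seed = 1)
  perf <- score_localizer(b, cohort_performances = c(1, 1, 1, 1))
  expect_equal(perf$performance, 1)
  expect_false(perf$excluded)
})

test_that("a cohort below size 2 warns and keeps the participant", {
  s <- generate_localizer_schedule(localizer_design(n_runs = 1), seed = 3)
  b <- simulate_localizer_behavior(s, seed = 1)
  expect_warning(perf <- score_localizer(b, cohort_performances = NULL),
                 "cohort")
  expect_false(perf$excluded)
})

test_that("calibrated defaults emulate the observed mean learning accuracy", {
  # analytic design mean of the default logistic curve is 59.35%; check the
  # stochastic generator against it over a cohort of simulated participants
  sched <- generate_association_schedule(task_design(), seed = 1)
  n_sim <- 400
  accs <- vapply(seq_len(n_sim), function(i)
    mean(simulate_behavior(sched, behavior_params(seed = i))$accuracy),
    numeric(1))
  se <- sd(accs) / sqrt(n_sim)
  expect_lt(abs(mean(accs) - 0.5935), 3 * se)
})
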