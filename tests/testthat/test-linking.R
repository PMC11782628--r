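test_that("transition coding follows the demand/success rules exactly", {
  trials <- data.frame(face_id = 1, presentation = 1:4,
                       accuracy = c(0, 0, 1, 1))
  fac <- code_factors(trials)
  expect_equal(fac$transition[1:3],
               c("ErrorError", "ErrorCorrect", "CorrectCorrect"))
  expect_equal(fac$demand[1:3], c(1L, 1L, 0L))
  expect_equal(fac$success[1:3], c(0L, 1L, 1L))
  expect_true(all(fac$included[1:3]))
  # the last presentation has no transition
  expect_true(is.na(fac$transition[4]))
  expect_false(fac$included[4])
  # CorrectError is always excluded
  ce <- code_factors(data.frame(face_id = 1, presentation = 1:2,
                                accuracy = c(1, 0)))
  expect_equal(ce$transition[1], "CorrectError")
  expect_false(ce$included[1])
  expect_match(ce$reason[1], "CorrectError")
})

test_that("factor invariants hold on generated behavioral data", {
  for (seed in c(3, 14)) {
    sched <- generate_association_schedule(task_design(), seed = seed)
    b <- simulate_behavior(sched, behavior_params(seed = seed + 1))
    fac <- code_factors(b)
    inc <- fac[fac$included, ]
    expect_true(all((inc$demand == 0) == (inc$transition == "CorrectCorrect")))
    expect_true(all((inc$success == 0) == (inc$transition == "ErrorError")))
    expect_false(any(inc$transition == "CorrectError"))
    # excluded trials are exactly last presentations and CorrectError
    exc <- fac[!fac$included, ]
    expect_true(all(is.na(exc$transition) |
                      exc$transition == "CorrectError"))
  }
})

test_that("orphan trials (face never re-presented) are excluded", {
  trials <- data.frame(face_id = c(1, 2, 1), presentation = c(1, 1, 2),
                       accuracy = c(1, 1, 1))
  fac <- code_factors(trials)
  expect_false(fac$included[2])
  expect_match(fac$reason[2], "no next presentation")
})

test_that("the mixed model recovers injected probability-scale effects", {
  ev <- simulate_evidence(12, demand_effect = 0.06, success_effect = 0.03,
                          seed = 21)
  fit <- fit_mixed_model(ev)
  co <- fit$coefficients
  d <- co[co$term == "demand", ]
  s <- co[co$term == "success", ]
  expect_gt(d$estimate, 0.02)
  expect_gt(d$z, 2)
  expect_true(d$ci_lower < 0.06 && 0.06 < d$ci_upper + 0.02)
  expect_gt(s$estimate, 0)
  expect_equal(fit$n_participants, 12L)
})

test_that("adding a constant to all probabilities moves only the intercept", {
  ev <- simulate_evidence(8, seed = 5, base = 0.3)
  f1 <- fit_mixed_model(ev)
  ev2 <- ev
  ev2$face_probability <- ev2$face_probability + 0.1
  f2 <- fit_mixed_model(ev2)
  c1 <- f1$coefficients; c2 <- f2$coefficients
  expect_equal(c2$estimate[c2$term == "demand"],
               c1$estimate[c1$term == "demand"], tolerance = 1e-6)
  expect_equal(c2$estimate[c2$term == "success"],
               c1$estimate[c1$term == "success"], tolerance = 1e-6)
  expect_equal(c2$estimate[c2$term == "(Intercept)"],
               c1$estimate[c1$term == "(Intercept)"] + 0.1,
               tolerance = 1e-6)
})

test_that("null effects give coefficients centred on zero", {
  set.seed(9)
  ests <- t(replicate(30, {
    ev <- simulate_evidence(8, demand_effect = 0, success_effect = 0,
                            seed = sample.int(2^30, 1))
    co <- fit_mixed_model(ev)$coefficients
    c(co$estimate[co$term == "demand"], co$estimate[co$term == "success"])
  }))
  for (j in 1:2) {
    se <- sd(ests[, j]) / sqrt(nrow(ests))
    expect_lt(abs(mean(ests[, j])), 3 * se + 0.002)
  }
})

test_that("the control variant keeps the success effect without CorrectCorrect trials", {
  ev <- simulate_evidence(14, demand_effect = 0.04, success_effect = 0.05,
                          seed = 33)
  fit <- fit_mixed_model(ev)
  expect_false(is.null(fit$control))
  ctrl <- fit$control$coefficients
  expect_gt(ctrl$estimate[ctrl$term == "success"], 0)
})

test_that("the mixed model needs two participants and both factor levels", {
  ev <- simulate_evidence(1, seed = 2)
  expect_error(fit_mixed_model(ev), "2 participants")
})

test_that("whole-brain evidence regression finds a planted voxel", {
  set.seed(41)
  n_trials <- 90; n_vox <- 120; n_sub <- 6
  beta <- list(); evidence <- list()
  for (p in seq_len(n_sub)) {
    B <- matrix(rnorm(n_trials * n_vox), n_trials, n_vox)
    ev <- 0.4 + 0.1 * scale(B[, 7]) + rnorm(n_trials, sd = 0.02)
    beta[[p]] <- B
    evidence[[p]] <- data.frame(face_probability = as.vector(ev))
  }
  wb <- wholebrain_evidence_regression(beta, evidence)
  expect_equal(which.max(wb$group$z), 7L)
  # scale invariance: rescaling evidence leaves the z map unchanged
  ev_scaled <- lapply(evidence, function(d) {
    d$face_probability <- d$face_probability * 3
    d
  })
  wb2 <- wholebrain_evidence_regression(beta, ev_scaled)
  expect_equal(wb2$group$z, wb$group$z, tolerance = 1e-10)
})

test_that("participants with constant evidence are dropped with a warning", {
  set.seed(42)
  beta <- replicate(4, matrix(rnorm(50 * 10), 50, 10), simplify = FALSE)
  evidence <- lapply(1:4, function(p)
    data.frame(face_probability = if (p == 2) rep(0.5, 50) else runif(50)))
  expect_warning(wb <- wholebrain_evidence_regression(beta, evidence),
                 "constant evidence")
  expect_equal(wb$dropped, 2L)
  expect_equal(nrow(wb$participant_slopes), 3L)
})
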