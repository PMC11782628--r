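test_that("a convolved event regressor peaks where the HRF oracle says", {
  # independent oracle: difference-of-gammas evaluated on a fine grid,
  # convolved with a 1 s boxcar by direct summation
  dt <- 0.01
  tt <- seq(0, 32, by = dt)
  hrf <- dgamma(tt, shape = 5.2 / 0.9 + 1, scale = 0.9) -
    0.35 * dgamma(tt, shape = 10.8 / 0.9 + 1, scale = 0.9)
  box <- as.numeric(tt <= 1)
  conv <- stats::convolve(c(box, rep(0, length(hrf))),
                          rev(c(hrf, rep(0, length(box)))), type = "open")
  oracle_peak <- (which.max(conv[seq_along(tt)]) - 1) * dt

  ev <- data.frame(category = "face", onset_stimulus = 0, dur_stimulus = 1,
                   run = 1, trial = 1)
  des <- build_design(ev, NULL, tr = 0.5, n_frames = 60,
                      variant = "localizer", drift_cutoff = NULL)
  col <- des$matrix[, "stimulus_face"]
  pkg_peak <- (which.max(col) - 1) * 0.5
  expect_lt(abs(pkg_peak - oracle_peak), 0.5)
  expect_gt(oracle_peak, 5)
  expect_lt(oracle_peak, 6.5)
})

test_that("model variants expose the study's condition sets", {
  s <- generate_association_schedule(task_design(), seed = 3)
  b <- simulate_behavior(s, behavior_params(seed = 5))
  run1 <- b[b$run == 1, ]
  nf <- ceiling((max(run1$onset_iti + run1$dur_iti) + 16) / 2)
  d1 <- build_design(run1, NULL, tr = 2, n_frames = nf,
                     variant = "recall_confidence_feedback")
  expect_true(any(startsWith(d1$event_cols, "feedback_")))
  expect_false(any(startsWith(d1$event_cols, "encoding_")))
  d2 <- build_design(run1, NULL, tr = 2, n_frames = nf,
                     variant = "recall_confidence_encoding")
  expect_false(any(startsWith(d2$event_cols, "feedback_")))
  expect_true(any(startsWith(d2$event_cols, "encoding_")))
  expect_true(any(startsWith(d2$event_cols, "recall_")))
  expect_equal(sum(d1$matrix[, "intercept"] == 1), nf)
  # determinism: identical inputs give identical matrices and column order
  d1b <- build_design(run1, NULL, tr = 2, n_frames = nf,
                      variant = "recall_confidence_feedback")
  expect_identical(d1$matrix, d1b$matrix)
})

test_that("an eventless design holds only confounds, drift and intercept", {
  conf <- matrix(rnorm(40), 20, 2)
  des <- build_design(data.frame(), conf, tr = 2, n_frames = 20,
                      variant = "localizer")
  expect_equal(length(des$event_cols), 0L)
  expect_equal(ncol(des$matrix), 2 + length(des$drift_cols) + 1)
})

test_that("noise-free simulated data are inverted exactly by the matching GLM", {
  ld <- localizer_design(n_runs = 1)
  sched <- simulate_localizer_behavior(
    generate_localizer_schedule(ld, seed = 7), seed = 2)
  pat <- pattern_spec(seed = 5)
  sim <- simulate_bold(sched, pat, noise_free(), ld)
  vol <- sim$runs[[1]]
  des <- build_design(sched, NULL, tr = ld$tr, n_frames = dim(vol$data)[4],
                      variant = "localizer", drift_cutoff = NULL)
  fit <- fit_glm(vol, des)
  expect_lt(max(abs(fit$betas["stimulus_face", pat$roi] -
                      pat$face_pattern) / abs(pat$face_pattern)), 1e-8)
  expect_lt(max(abs(fit$betas["stimulus_house", pat$roi] -
                      pat$house_pattern) / abs(pat$house_pattern)), 1e-8)
  # voxels outside the ROI carry no signal
  expect_lt(max(abs(fit$betas[, -pat$roi])), 1e-8)
})

test_that("a confound orthogonal to the design leaves event betas unchanged", {
  ld <- localizer_design(n_runs = 1)
  sched <- simulate_localizer_behavior(
    generate_localizer_schedule(ld, seed = 7), seed = 2)
  pat <- pattern_spec(seed = 5)
  sim <- simulate_bold(sched, pat, noise_spec(sigma = 0.4, seed = 9,
                                              n_drift = 0, n_confounds = 0),
                       ld)
  vol <- sim$runs[[1]]
  nf <- dim(vol$data)[4]
  des <- build_design(sched, NULL, tr = ld$tr, n_frames = nf,
                      variant = "localizer", drift_cutoff = NULL)
  fit0 <- fit_glm(vol, des)
  set.seed(1)
  raw <- rnorm(nf)
  ortho <- residuals(lm(raw ~ des$matrix - 1))
  des2 <- build_design(sched, matrix(ortho, dimnames = list(NULL, "c1")),
                       tr = ld$tr, n_frames = nf, variant = "localizer",
                       drift_cutoff = NULL)
  fit2 <- fit_glm(vol, des2)
  expect_equal(fit2$betas["stimulus_face", ], fit0$betas["stimulus_face", ],
               tolerance = 1e-10)
})

test_that("OLS betas are unbiased under AR(1) noise", {
  set.seed(44)
  n <- 120
  ft <- (0:(n - 1)) * 2
  x <- memtrace:::convolve_events(seq(5, 200, by = 14), 1.5, ft)
  X <- cbind(x = x, intercept = 1)
  errs <- replicate(200, {
    e <- as.numeric(arima.sim(list(ar = 0.4), n = n, sd = 1))
    y <- 2 * x + e
    fit_glm(matrix(y), X)$betas["x", 1] - 2
  })
  mc_half_width <- 3 * sd(errs) / sqrt(length(errs))
  expect_lt(abs(mean(errs)), mc_half_width)
})

test_that("contrasts are linear, antisymmetric and null on zero weights", {
  ld <- localizer_design(n_runs = 1)
  sched <- simulate_localizer_behavior(
    generate_localizer_schedule(ld, seed = 7), seed = 2)
  pat <- pattern_spec(seed = 5)
  sim <- simulate_bold(sched, pat, noise_spec(sigma = 0.5, seed = 3), ld)
  vol <- sim$runs[[1]]
  des <- build_design(sched, sim$ground_truth$confounds[[1]], tr = ld$tr,
                      n_frames = dim(vol$data)[4], variant = "localizer")
  fit <- fit_glm(vol, des)
  zero <- contrast(fit, c(stimulus_face = 0, stimulus_house = 0))
  expect_true(all(zero$effect == 0))
  expect_true(all(zero$t == 0))
  fh <- contrast(fit, c(stimulus_face = 1, stimulus_house = -1))
  hf <- contrast(fit, c(stimulus_face = -1, stimulus_house = 1))
  expect_equal(fh$effect, -hf$effect)
  expect_equal(fh$t, -hf$t)
  w1 <- contrast(fit, c(stimulus_face = 1))
  w2 <- contrast(fit, c(stimulus_house = 1))
  sum12 <- contrast(fit, c(stimulus_face = 1, stimulus_house = 1))
  expect_equal(sum12$effect, w1$effect + w2$effect, tolerance = 1e-12)
  expect_error(contrast(fit, c(not_a_column = 1)), "missing-column")
  # r-squared is the t-based effect size bounded by [0, 1]
  expect_true(all(fh$r_squared >= 0 & fh$r_squared <= 1))
  expect_equal(as.vector(fh$r_squared),
               as.vector(fh$t^2 / (fh$t^2 + fh$df)), tolerance = 1e-12)
})

test_that("a planted face > house contrast localises to the ROI", {
  ld <- localizer_design()
  sched <- simulate_localizer_behavior(
    generate_localizer_schedule(ld, seed = 7), seed = 2)
  pat <- pattern_spec(seed = 5)
  sim <- simulate_bold(sched, pat, noise_spec(sigma = 0.05,
                                              ar_coefficient = 0,
                                              n_drift = 0, n_confounds = 0,
                                              seed = 3), ld)
  vol <- sim$runs[[1]]
  des <- build_design(sched[sched$run == 1, ], NULL, tr = ld$tr,
                      n_frames = dim(vol$data)[4], variant = "localizer",
                      drift_cutoff = NULL)
  fit <- fit_glm(vol, des)
  fh <- contrast(fit, c(stimulus_face = 1, stimulus_house = -1))
  truth <- pat$face_pattern - pat$house_pattern
  expect_equal(as.vector(fh$effect)[pat$roi], truth, tolerance = 0.15)
  expect_lt(max(abs(as.vector(fh$effect)[-pat$roi])), 0.1)
})

test_that("the t-to-z map preserves two-sided tail probability", {
  for (df in c(5, 29, 120)) {
    t_vals <- c(-8, -3.2, -0.7, 0, 0.5, 2.4, 6, 15)
    z <- t_to_z(t_vals, df)
    p_t <- 2 * pt(-abs(t_vals), df)
    p_z <- 2 * pnorm(-abs(z))
    expect_lt(max(abs(p_t - p_z)), 1e-10)
    expect_equal(sign(z), sign(t_vals))
  }
  # extreme statistics stay finite and ordered
  z_big <- t_to_z(c(500, 1000), 29)
  expect_true(all(is.finite(z_big)))
  expect_true(diff(z_big) > 0)
})

test_that("rank-deficient designs are refused with the offending column named", {
  X <- cbind(a = rnorm(20), b = 1:20, intercept = 1)
  X <- cbind(X, b_copy = X[, "b"])
  expect_error(fit_glm(matrix(rnorm(20)), X), "singular-design.*b")
})

test_that("VIF diagnostics match the definitional oracle and flag duplicates", {
  set.seed(2)
  n <- 80
  ev <- matrix(rnorm(n * 4), n, 4,
               dimnames = list(NULL, paste0("reg", 1:4)))
  ev[, 2] <- ev[, 1] * 0.7 + ev[, 2] * 0.3
  des <- structure(list(matrix = cbind(ev, intercept = 1),
                        event_cols = colnames(ev)),
                   class = "design_matrix")
  diag_res <- collinearity_diagnostics(des)
  # oracle: per-column OLS R^2
  for (j in 1:4) {
    fit <- lm(ev[, j] ~ ev[, -j])
    vif_oracle <- 1 / (1 - summary(fit)$r.squared)
    expect_equal(diag_res$vif$vif[j], vif_oracle, tolerance = 1e-8)
  }
  # centred orthogonalised columns give VIF 1 and |r| ~ 0
  orth <- qr.Q(qr(scale(matrix(rnorm(n * 3), n, 3), scale = FALSE)))
  colnames(orth) <- paste0("o", 1:3)
  des_o <- structure(list(matrix = cbind(orth, intercept = 1),
                          event_cols = colnames(orth)),
                     class = "design_matrix")
  do_ <- collinearity_diagnostics(des_o)
  expect_equal(do_$vif$vif, rep(1, 3), tolerance = 1e-8)
  expect_true(all(do_$vif$max_abs_r < 1e-8))
  expect_true(all(do_$vif$flag == "none"))
  # duplicated regressor: infinite VIF, high flag, |r| = 1
  dup <- cbind(ev[, 1:2], dup1 = ev[, 1])
  colnames(dup)[1:2] <- c("reg1", "reg2")
  des_d <- structure(list(matrix = cbind(dup, intercept = 1),
                          event_cols = colnames(dup)),
                     class = "design_matrix")
  dd <- collinearity_diagnostics(des_d)
  expect_true(is.infinite(dd$vif$vif[1]))
  expect_equal(dd$vif$flag[1], "high")
  expect_true(dd$vif$r_flag[1])
  expect_equal(max(abs(dd$correlations["reg1", "dup1"])), 1)
})
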