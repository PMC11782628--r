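test_that("linearly separable planted patterns decode perfectly in every fold", {
  series <- separable_fixture()$series
  cv <- cross_validate(series, mvpa_config())
  expect_equal(cv$folds$balanced_accuracy, rep(1, 5))
  expect_equal(cv$mean_balanced_accuracy, 1)
})

test_that("predicted classes agree with the 0.5 probability threshold", {
  lf <- localizer_fixture()
  model <- fit_full_model(lf$series, mvpa_config())
  ev <- predict_evidence(model, lf$series)
  expect_true(all(ev$face_probability >= 0 & ev$face_probability <= 1))
  expect_equal(ev$predicted_class,
               ifelse(ev$face_probability >= 0.5, "face", "house"))
})

test_that("feature selection and scaling use training folds only", {
  series <- localizer_fixture()$series
  cv <- cross_validate(series, mvpa_config())
  runs <- sort(unique(series$trial_meta$run))
  for (r in runs[1:2]) {
    test_rows <- series$trial_meta$run == r
    Xtr <- series$matrix[!test_rows, , drop = FALSE]
    ytr <- series$trial_meta$category[!test_rows]
    scaler <- memtrace:::fit_scaler(Xtr)
    Xtr_s <- memtrace:::apply_scaler(Xtr, scaler)
    feats <- memtrace:::select_features(Xtr_s, ytr, 14)
    par <- memtrace:::train_platt_svm(Xtr_s[, feats], ytr, 1, 1L)
    Xte_s <- memtrace:::apply_scaler(series$matrix[test_rows, ], scaler)
    p <- memtrace:::platt_probability(par, Xte_s[, feats])
    pred <- ifelse(p >= 0.5, "face", "house")
    acc <- memtrace:::balanced_accuracy(
      series$trial_meta$category[test_rows], pred)
    expect_equal(cv$folds$balanced_accuracy[cv$folds$run == r],
                 acc$balanced)
  }
})

test_that("a training fold missing a class is skipped with a record", {
  series <- localizer_fixture()$series
  two_runs <- series$trial_meta$run <= 2
  s2 <- list(matrix = series$matrix[two_runs, ],
             trial_meta = series$trial_meta[two_runs, ],
             mask = series$mask, epoch = series$epoch)
  class(s2) <- "beta_series"
  s2$trial_meta$category[s2$trial_meta$run == 1] <- "face"
  cv <- cross_validate(s2, mvpa_config(n_features = 5))
  expect_equal(length(cv$skipped), 1L)
  expect_equal(cv$skipped[[1]]$run, 2)
})

test_that("the full model applies deterministically and round-trips JSON", {
  lf <- localizer_fixture()
  model <- fit_full_model(lf$series, mvpa_config())
  p1 <- predict_evidence(model, lf$series)$face_probability
  p2 <- predict_evidence(model, lf$series)$face_probability
  expect_identical(p1, p2)
  path <- tempfile(fileext = ".json")
  save_evidence_model(model, path)
  reloaded <- load_evidence_model(path)
  p3 <- predict_evidence(reloaded, lf$series)$face_probability
  expect_identical(p1, p3)
})

test_that("the training face centroid is classified as a face", {
  lf <- localizer_fixture()
  model <- fit_full_model(lf$series, mvpa_config())
  centroid <- colMeans(
    lf$series$matrix[lf$series$trial_meta$category == "face", ])
  s1 <- list(matrix = matrix(centroid, 1), trial_meta = data.frame(run = 1),
             mask = lf$series$mask, epoch = "stimulus")
  class(s1) <- "beta_series"
  ev <- predict_evidence(model, s1)
  expect_gt(ev$face_probability, 0.5)
  expect_equal(ev$predicted_class, "face")
})

test_that("a mask mismatch raises a feature-space error", {
  lf <- localizer_fixture()
  model <- fit_full_model(lf$series, mvpa_config())
  wrong <- lf$series
  wrong$mask <- wrong$mask + 1L
  expect_error(predict_evidence(model, wrong), "feature-space")
})

test_that("permuted labels decode at chance on average", {
  series <- localizer_fixture()$series
  set.seed(13)
  accs <- replicate(40, {
    s2 <- series
    s2$trial_meta$category <- sample(s2$trial_meta$category)
    cross_validate(s2, mvpa_config())$mean_balanced_accuracy
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.02)
})

test_that("calibrated probabilities track empirical face frequency monotonically", {
  # many trials from the separable generator, predicted by a model trained on
  # the noisier fixture, binned by predicted probability
  lf <- localizer_fixture()
  model <- fit_full_model(lf$series, mvpa_config())
  ev <- predict_evidence(model, lf$series)
  truth <- lf$series$trial_meta$category == "face"
  bins <- cut(ev$face_probability, breaks = c(0, 0.35, 0.65, 1),
              include.lowest = TRUE)
  freq <- tapply(truth, bins, mean)
  freq <- freq[!is.na(freq)]
  expect_true(all(diff(freq) >= 0))
})

test_that("probability validity uses rank correlation with its invariances", {
  n_face <- c(0, 1, 3, 5, 8, 9) # strictly increasing prediction fractions
  ev <- do.call(rbind, lapply(1:6, function(i)
    data.frame(participant = sprintf("p%d", i), epoch = "recall",
               face_probability = 0.2 + 0.1 * i,
               predicted_class = rep(c("face", "house"),
                                     c(n_face[i], 10 - n_face[i])))))
  val <- validate_probability_measure(ev)
  expect_equal(val$rho, 1)
  # invariance under a strictly monotone transform of the probabilities
  ev2 <- ev
  ev2$face_probability <- qlogis(ev2$face_probability)
  expect_equal(validate_probability_measure(ev2)$rho, val$rho)
  # independent pairs: rho centred on zero
  set.seed(17)
  rhos <- replicate(200, {
    e <- data.frame(participant = sprintf("p%d", 1:8), epoch = "x",
                    face_probability = runif(8),
                    predicted_class = sample(c("face", "house"), 8, TRUE))
    suppressWarnings(validate_probability_measure(e)$rho)
  })
  rhos <- rhos[!is.na(rhos)]
  expect_lt(abs(mean(rhos)), 3 * sd(rhos) / sqrt(length(rhos)) + 0.02)
})
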