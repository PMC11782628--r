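#' MVPA configuration
#'
#' Cross-validated face/house decoding settings: per-feature z-scoring fit on
#' training trials only, univariate selection of the `n_features` voxels with
#' the strongest positive (face > house) one-way F effects, and a balanced
#' L2-regularised linear support vector machine (C = `svm_cost`) with Platt
#' probability scaling. With 70 training trials and the default 14 features
#' the samples-per-feature ratio is 5.
#'
#' @param n_features voxels kept by feature selection.
#' @param svm_cost SVM regularisation constant C.
#' @param seed seed for the internal Platt-calibration cross-validation.
#' @return object of class `mvpa_config`.
#' @export
mvpa_config <- function(n_features = 14, svm_cost = 1, seed = 1L) {
  stopifnot(n_features >= 1, svm_cost > 0)
  structure(list(n_features = n_features, svm_cost = svm_cost,
                 seed = as.integer(seed)), class = "mvpa_config")
}

# One-way F statistics per column for a two-class label, with the sign
# constraint that "positive" means the face mean exceeds the house mean.
anova_f_scores <- function(X, y) {
  face <- y == "face"
  n1 <- sum(face); n2 <- sum(!face); n <- n1 + n2
  m1 <- colMeans(X[face, , drop = FALSE])
  m2 <- colMeans(X[!face, , drop = FALSE])
  gm <- colMeans(X)
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- colSums((X[face, , drop = FALSE] -
                    matrix(m1, n1, ncol(X), byrow = TRUE))^2) +
    colSums((X[!face, , drop = FALSE] -
               matrix(m2, n2, ncol(X), byrow = TRUE))^2)
  f <- ifelse(ssw > 0, ssb / 1 / (ssw / (n - 2)), Inf)
  list(f = f, face_preferring = m1 > m2)
}

# Keep the n strongest face-preferring (face mean > house mean) voxels by F
# statistic; when fewer than n positive voxels exist (possible under label
# permutation or a degenerate ROI) the remaining slots are filled by F rank
# irrespective of sign so downstream fits stay defined.
select_features <- function(X, y, n_features) {
  sc <- anova_f_scores(X, y)
  pos <- which(sc$face_preferring)
  pos <- pos[order(sc$f[pos], decreasing = TRUE)]
  sel <- pos[seq_len(min(n_features, length(pos)))]
  if (length(sel) < n_features) {
    rest <- setdiff(order(sc$f, decreasing = TRUE), sel)
    sel <- c(sel, rest[seq_len(n_features - length(sel))])
  }
  sel[seq_len(min(n_features, ncol(X)))]
}

fit_scaler <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, `/`)
}

# Train a balanced Platt-scaled linear SVM and freeze it to plain numbers:
# weights, offset, sigmoid parameters and an orientation flag checked against
# libsvm's own probability output on the training data.
train_platt_svm <- function(Xs, y, cost, seed) {
  y <- factor(y, levels = c("face", "house"))
  tab <- table(y)
  cw <- as.numeric(length(y) / (2 * tab)); names(cw) <- names(tab)
  m <- with_seed(seed,
    e1071::svm(Xs, y, kernel = "linear", cost = cost, scale = FALSE,
               probability = TRUE, class.weights = cw))
  w <- as.vector(t(m$coefs) %*% m$SV)
  d_train <- as.vector(Xs %*% w) - m$rho
  p_manual <- 1 / (1 + exp(m$probA * d_train + m$probB))
  p_ref <- attr(stats::predict(m, Xs, probability = TRUE),
                "probabilities")[, "face"]
  flip <- mean(abs(p_manual - p_ref)) > mean(abs((1 - p_manual) - p_ref))
  list(w = w, rho = m$rho, probA = m$probA, probB = m$probB, flip = flip)
}

platt_probability <- function(svm_par, Xs) {
  d <- as.vector(Xs %*% svm_par$w) - svm_par$rho
  p <- 1 / (1 + exp(svm_par$probA * d + svm_par$probB))
  if (svm_par$flip) 1 - p else p
}

balanced_accuracy <- function(truth, predicted) {
  classes <- c("face", "house")
  recalls <- vapply(classes, function(cl) {
    sel <- truth == cl
    if (!any(sel)) return(NA_real_)
    mean(predicted[sel] == cl)
  }, numeric(1))
  list(balanced = mean(recalls, na.rm = TRUE),
       face = recalls[["face"]], house = recalls[["house"]])
}

#' Leave-one-run-out cross-validation of face/house decoding
#'
#' Per fold: the scaler and the positive-F feature selection are fit on the
#' training runs only and applied to the left-out run, then a balanced linear
#' SVM predicts the held-out trials. Balanced accuracy averages the face and
#' house recalls, and the per-class accuracies and their difference are
#' reported so category preference can be checked.
#'
#' @param series a [extract_roi()] betaseries whose `trial_meta` has `run`
#'   and `category` columns.
#' @param config an [mvpa_config()].
#' @return object of class `cv_result`: `folds` data.frame (run,
#'   balanced_accuracy, face_accuracy, house_accuracy, n_test),
#'   `mean_balanced_accuracy`, `mean_class_difference`, `skipped`.
#' @export
cross_validate <- function(series, config = mvpa_config()) {
  stopifnot(inherits(series, "beta_series"),
            all(c("run", "category") %in% names(series$trial_meta)))
  runs <- sort(unique(series$trial_meta$run))
  if (length(runs) < 2) stop("need at least 2 runs", call. = FALSE)
  rows <- list(); skipped <- list()
  for (r in runs) {
    test <- series$trial_meta$run == r
    Xtr <- series$matrix[!test, , drop = FALSE]
    ytr <- series$trial_meta$category[!test]
    if (length(unique(ytr)) < 2) {
      skipped[[length(skipped) + 1]] <- list(run = r,
                                             reason = "training fold missing a class")
      next
    }
    if (config$n_features > nrow(Xtr))
      stop("config error: n_features exceeds training trials", call. = FALSE)
    scaler <- fit_scaler(Xtr)
    Xtr_s <- apply_scaler(Xtr, scaler)
    feats <- select_features(Xtr_s, ytr, config$n_features)
    par <- train_platt_svm(Xtr_s[, feats, drop = FALSE], ytr,
                           config$svm_cost, config$seed)
    Xte_s <- apply_scaler(series$matrix[test, , drop = FALSE], scaler)
    p <- platt_probability(par, Xte_s[, feats, drop = FALSE])
    pred <- ifelse(p >= 0.5, "face", "house")
    acc <- balanced_accuracy(series$trial_meta$category[test], pred)
    rows[[length(rows) + 1]] <- data.frame(
      run = r, balanced_accuracy = acc$balanced,
      face_accuracy = acc$face, house_accuracy = acc$house,
      n_test = sum(test))
  }
  folds <- do.call(rbind, rows)
  structure(list(folds = folds,
                 mean_balanced_accuracy = mean(folds$balanced_accuracy),
                 mean_class_difference = mean(folds$face_accuracy -
                                                folds$house_accuracy,
                                              na.rm = TRUE),
                 skipped = skipped), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Leave-one-run-out decoding: mean balanced accuracy %.2f%% over %d folds\n",
              100 * x$mean_balanced_accuracy, nrow(x$folds)))
  invisible(x)
}

#' Fit the full face-evidence model on all runs
#'
#' Scaling, positive-F feature selection and the balanced Platt-scaled linear
#' SVM are fit on every trial of the series (typically the correct-rejection
#' localizer trials). The returned model is a frozen numeric transform chain
#' (center/scale, feature indices, SVM weights and Platt sigmoid), so it can
#' be serialised to JSON and reapplied bit-identically.
#'
#' @param series a [extract_roi()] betaseries with `category` metadata.
#' @param config an [mvpa_config()].
#' @return object of class `face_evidence_model`.
#' @export
fit_full_model <- function(series, config = mvpa_config()) {
  stopifnot(inherits(series, "beta_series"),
            "category" %in% names(series$trial_meta))
  y <- series$trial_meta$category
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  if (config$n_features > nrow(series$matrix))
    stop("config error: n_features exceeds available trials", call. = FALSE)
  scaler <- fit_scaler(series$matrix)
  Xs <- apply_scaler(series$matrix, scaler)
  feats <- select_features(Xs, y, config$n_features)
  par <- train_platt_svm(Xs[, feats, drop = FALSE], y, config$svm_cost,
                         config$seed)
  structure(list(center = scaler$center, scale = scaler$scale,
                 features = feats, svm = par, mask = series$mask,
                 n_train = nrow(series$matrix), config = config),
            class = "face_evidence_model")
}

#' @export
print.face_evidence_model <- function(x, ...) {
  cat(sprintf("face_evidence_model: %d features over a %d-voxel mask, trained on %d trials\n",
              length(x$features), length(x$mask), x$n_train))
  invisible(x)
}

#' Predict calibrated face-processing evidence for new trials
#'
#' Applies the frozen scaler, feature selection and Platt-scaled SVM of a
#' [fit_full_model()] to a betaseries over the same mask; each trial gets a
#' calibrated face-class probability and a predicted class (`face` when the
#' probability is >= 0.5; exact ties go to face by convention).
#'
#' @param model a `face_evidence_model`.
#' @param series a [extract_roi()] betaseries over the same voxel mask.
#' @param epoch epoch label for the output.
#' @param participant optional participant ID column value.
#' @return data.frame (evidence table): `trial_id`, `run`, `epoch`,
#'   `face_probability`, `predicted_class` (+ `participant` if given).
#' @export
predict_evidence <- function(model, series, epoch = series$epoch,
                             participant = NULL) {
  stopifnot(inherits(model, "face_evidence_model"),
            inherits(series, "beta_series"))
  if (!identical(as.integer(model$mask), as.integer(series$mask)))
    stop("feature-space error: series mask does not match the model's mask",
         call. = FALSE)
  Xs <- apply_scaler(series$matrix, list(center = model$center,
                                         scale = model$scale))
  p <- platt_probability(model$svm, Xs[, model$features, drop = FALSE])
  out <- data.frame(trial_id = seq_len(nrow(series$matrix)),
                    run = series$trial_meta$run %||%
                      rep(NA_integer_, nrow(series$matrix)),
                    epoch = epoch,
                    face_probability = p,
                    predicted_class = ifelse(p >= 0.5, "face", "house"))
  if (!is.null(participant)) out$participant <- participant
  out
}

#' Validate the probability measure against prediction rates
#'
#' Per epoch, computes the Spearman rank correlation across participants
#' between the mean calibrated face probability and the fraction of trials
#' predicted as faces — the two should agree if the probability carries the
#' same information as the hard classification rate.
#'
#' @param evidence evidence table with `participant`, `epoch`,
#'   `face_probability`, `predicted_class`.
#' @return data.frame: `epoch`, `rho`, `p`, `n_participants`.
#' @export
validate_probability_measure <- function(evidence) {
  stopifnot(all(c("participant", "epoch", "face_probability",
                  "predicted_class") %in% names(evidence)))
  out <- lapply(split(evidence, evidence$epoch), function(d) {
    agg_p <- tapply(d$face_probability, d$participant, mean)
    agg_r <- tapply(d$predicted_class == "face", d$participant, mean)
    n <- length(agg_p)
    if (n < 5) stop("need >= 5 participants", call. = FALSE)
    if (stats::sd(agg_p) == 0 || stats::sd(agg_r) == 0) {
      warning("constant values: Spearman correlation undefined")
      return(data.frame(epoch = d$epoch[1], rho = NA_real_, p = NA_real_,
                        n_participants = n))
    }
    ct <- suppressWarnings(stats::cor.test(agg_p, agg_r,
                                           method = "spearman"))
    data.frame(epoch = d$epoch[1], rho = unname(ct$estimate),
               p = ct$p.value, n_participants = n)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Save / load a face-evidence model as JSON
#'
#' The model is plain numbers, so the round trip is exact (full double
#' precision is serialised) and reloaded models produce bit-identical
#' probabilities.
#'
#' @param model a `face_evidence_model`.
#' @param path file path.
#' @return `save_evidence_model` returns `path` invisibly;
#'   `load_evidence_model` returns the model.
#' @export
save_evidence_model <- function(model, path) {
  # doubles are serialised as 17-significant-digit strings: shortest exact
  # decimal representation, so the reloaded model is bit-identical
  full <- function(x) sprintf("%.17g", x)
  obj <- list(center = full(model$center), scale = full(model$scale),
              features = model$features, mask = model$mask,
              n_train = model$n_train,
              svm = lapply(model$svm[c("w", "rho", "probA", "probB")], full),
              flip = model$svm$flip,
              config = list(n_features = model$config$n_features,
                            svm_cost = model$config$svm_cost,
                            seed = model$config$seed),
              version = 1L)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_evidence_model
#' @export
load_evidence_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(center = as.numeric(obj$center),
                 scale = as.numeric(obj$scale),
                 features = as.integer(obj$features),
                 svm = list(w = as.numeric(obj$svm$w),
                            rho = as.numeric(obj$svm$rho),
                            probA = as.numeric(obj$svm$probA),
                            probB = as.numeric(obj$svm$probB),
                            flip = isTRUE(obj$flip)),
                 mask = as.integer(obj$mask), n_train = obj$n_train,
                 config = mvpa_config(obj$config$n_features,
                                      obj$config$svm_cost,
                                      obj$config$seed)),
            class = "face_evidence_model")
}
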