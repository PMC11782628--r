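# Long-format (condition, onset, duration) event list for a GLM variant.
# Association-task conditions follow the study's condition system: recall
# split by accuracy x confidence, confidence selection by level, feedback by
# valence, encoding by the (current, next) recall transition of the same face.
events_to_conditions <- function(events, variant) {
  if (variant == "localizer") {
    stopifnot(all(c("category", "onset_stimulus", "dur_stimulus") %in%
                    names(events)))
    return(data.frame(condition = paste0("stimulus_", events$category),
                      onset = events$onset_stimulus,
                      duration = events$dur_stimulus))
  }
  stopifnot(all(c("accuracy", "confidence") %in% names(events)))
  acc_lab <- ifelse(events$accuracy == 1, "Correct", "Error")
  conf_lab <- ifelse(events$confidence == "high", "ConfHigh", "ConfLow")
  recall <- data.frame(
    condition = paste0("recall_", acc_lab, "_", conf_lab),
    onset = events$onset_recall, duration = events$dur_recall)
  confid <- data.frame(
    condition = paste0("confidence_", ifelse(events$confidence == "high",
                                             "high", "low")),
    onset = events$onset_confidence, duration = events$dur_confidence)
  feedback <- data.frame(
    condition = paste0("feedback_", ifelse(events$accuracy == 1,
                                           "positive", "negative")),
    onset = events$onset_feedback, duration = events$dur_feedback)
  if (variant == "recall_confidence_feedback")
    return(rbind(recall, confid, feedback))
  fac <- code_factors(events)
  enc_lab <- ifelse(is.na(fac$transition), "Final", fac$transition)
  encoding <- data.frame(
    condition = paste0("encoding_", enc_lab),
    onset = events$onset_encoding, duration = events$dur_encoding)
  rbind(recall, confid, encoding)
}

# Discrete cosine drift basis with a high-pass cutoff (seconds).
cosine_drift <- function(frame_times, cutoff = 128) {
  n <- length(frame_times)
  duration <- max(frame_times) - min(frame_times)
  k_max <- max(0L, floor(2 * duration / cutoff))
  if (k_max == 0L) return(matrix(numeric(0), n, 0))
  i <- seq_len(n) - 1L
  basis <- sapply(seq_len(k_max), function(k)
    sqrt(2 / n) * cos(pi * (2 * i + 1) * k / (2 * n)))
  basis <- matrix(basis, n, k_max)
  colnames(basis) <- paste0("drift_", seq_len(k_max))
  basis
}

#' Build a first-level design matrix
#'
#' Convolves duration-matched event boxcars with the Glover HRF on an
#' oversampled grid, one regressor per condition of the requested model
#' variant, and appends confound columns, a cosine drift set (128 s high-pass
#' cutoff) and an intercept. Column order and values are deterministic.
#'
#' Variants: `"recall_confidence_feedback"` models recall, confidence and
#' feedback epochs; `"recall_confidence_encoding"` replaces the feedback
#' regressors (redundant with and temporally adjacent to encoding) with
#' transition-coded encoding regressors; `"localizer"` models the stimulus
#' epoch split by category.
#'
#' @param events an event table (association-task or localizer schedule with
#'   behavioral outcomes).
#' @param confounds optional numeric matrix/data.frame of nuisance regressors
#'   (one row per frame).
#' @param tr repetition time (s).
#' @param n_frames number of frames.
#' @param variant model variant (see Details).
#' @param drift_cutoff high-pass cutoff for the cosine set (s); `NULL`
#'   disables drift modelling.
#' @return object of class `design_matrix`: the numeric matrix plus column
#'   bookkeeping (`event_cols`, `confound_cols`, `drift_cols`).
#' @export
build_design <- function(events, confounds = NULL, tr, n_frames,
                         variant = c("recall_confidence_feedback",
                                     "recall_confidence_encoding",
                                     "localizer"),
                         drift_cutoff = 128) {
  variant <- match.arg(variant)
  frame_times <- (seq_len(n_frames) - 1) * tr
  cond <- if (nrow(events) > 0) events_to_conditions(events, variant)
          else data.frame(condition = character(), onset = numeric(),
                          duration = numeric())
  if (nrow(cond) > 0 &&
      max(cond$onset + cond$duration) > max(frame_times) + tr)
    warning("events extend beyond the scan; late responses are truncated")
  cond_names <- sort(unique(cond$condition))
  event_mat <- sapply(cond_names, function(cn) {
    sel <- cond$condition == cn
    convolve_events(cond$onset[sel], cond$duration[sel], frame_times)
  })
  event_mat <- matrix(event_mat, n_frames, length(cond_names),
                      dimnames = list(NULL, cond_names))
  if (ncol(event_mat) > 0) {
    zero_var <- apply(event_mat, 2, stats::sd) == 0
    if (any(zero_var)) {
      warning("dropping zero-variance event regressor(s): ",
              paste(cond_names[zero_var], collapse = ", "))
      event_mat <- event_mat[, !zero_var, drop = FALSE]
    }
  }
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    stopifnot(nrow(confounds) == n_frames)
    if (is.null(colnames(confounds)))
      colnames(confounds) <- paste0("confound_", seq_len(ncol(confounds)))
  } else confounds <- matrix(numeric(0), n_frames, 0)
  drift <- if (is.null(drift_cutoff)) matrix(numeric(0), n_frames, 0)
           else cosine_drift(frame_times, drift_cutoff)
  X <- cbind(event_mat, confounds, drift, intercept = 1)
  structure(list(matrix = X, frame_times = frame_times, tr = tr,
                 event_cols = colnames(event_mat),
                 confound_cols = colnames(confounds),
                 drift_cols = colnames(drift),
                 variant = variant),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix (%s): %d frames x %d columns (%d event, %d confound, %d drift, 1 intercept)\n",
              x$variant, nrow(x$matrix), ncol(x$matrix),
              length(x$event_cols), length(x$confound_cols),
              length(x$drift_cols)))
  invisible(x)
}

#' Fit a voxelwise ordinary least squares GLM
#'
#' Plain OLS per voxel (no prewhitening); residual degrees of freedom are
#' frames minus design rank. Rank-deficient designs are refused, naming the
#' offending columns.
#'
#' @param volumes a [vol4d()] or a frames x voxels matrix.
#' @param design a [build_design()] result or a plain numeric matrix.
#' @return object of class `glm_fit`: `betas` (columns x voxels), `sigma2`,
#'   `df`, `xtx_inv`, column names, and the spatial dims when known.
#' @export
fit_glm <- function(volumes, design) {
  X <- if (inherits(design, "design_matrix")) design$matrix else as.matrix(design)
  Y <- as_frame_matrix(volumes)
  stopifnot(nrow(Y) == nrow(X))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("singular-design: collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  betas <- qr.coef(qr_x, Y)
  resid <- Y - X %*% betas
  df <- nrow(X) - qr_x$rank
  sigma2 <- colSums(resid^2) / max(df, 1L)
  xtx_inv <- chol2inv(qr.R(qr_x))
  piv <- qr_x$pivot
  xtx_inv <- xtx_inv[order(piv), order(piv), drop = FALSE]
  rownames(betas) <- colnames(X)
  structure(list(betas = betas, sigma2 = sigma2, df = df,
                 xtx_inv = xtx_inv, columns = colnames(X),
                 dims = spatial_dim(volumes), tr = NULL),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("glm_fit: %d regressors x %d voxels, residual df = %d\n",
              nrow(x$betas), ncol(x$betas), x$df))
  invisible(x)
}

#' Compute a linear contrast of GLM coefficients
#'
#' Effect = weighted sum of betas; t = effect / SE with the OLS covariance;
#' z via a two-sided tail-probability-preserving t-to-z mapping; the
#' effect-size map `r_squared = t^2 / (t^2 + df)` and 95% CI bounds.
#'
#' @param fit a [fit_glm()] result.
#' @param weights named numeric vector; names must be design columns.
#'   Unnamed columns get weight zero.
#' @return object of class `contrast_result` with per-voxel `effect`, `se`,
#'   `t`, `z`, `r_squared`, `ci_lower`, `ci_upper`, `df` (3D arrays when the
#'   fit has spatial dims).
#' @export
contrast <- function(fit, weights) {
  stopifnot(inherits(fit, "glm_fit"), !is.null(names(weights)))
  missing <- setdiff(names(weights), fit$columns)
  if (length(missing) > 0)
    stop("missing-column: contrast references absent column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  w <- stats::setNames(numeric(length(fit$columns)), fit$columns)
  w[names(weights)] <- weights
  effect <- as.vector(t(w) %*% fit$betas)
  wvar <- as.numeric(t(w) %*% fit$xtx_inv %*% w)
  se <- sqrt(fit$sigma2 * wvar)
  t_stat <- ifelse(se > 0, effect / se, ifelse(effect == 0, 0,
                                               sign(effect) * T_CAP))
  z <- t_to_z(t_stat, fit$df)
  r2 <- t_stat^2 / (t_stat^2 + fit$df)
  hw <- stats::qt(0.975, fit$df) * se
  d <- fit$dims
  structure(list(effect = as_volume(effect, d), se = as_volume(se, d),
                 t = as_volume(t_stat, d), z = as_volume(z, d),
                 r_squared = as_volume(r2, d),
                 ci_lower = as_volume(effect - hw, d),
                 ci_upper = as_volume(effect + hw, d),
                 df = fit$df, weights = w, dims = d),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("contrast_result: df = %d, max |z| = %.2f\n", x$df,
              max(abs(x$z))))
  invisible(x)
}

#' Collinearity diagnostics for convolved event regressors
#'
#' Variance inflation factors (VIF_j = 1 / (1 - R^2_j) from regressing event
#' column j on the other event columns plus an intercept) and pairwise
#' Pearson correlations. Flags follow common design-efficiency practice:
#' VIF <= 5 none, 5-10 moderate, >= 10 high; a correlation flag is raised at
#' |r| >= 0.90. Perfectly collinear columns give an infinite VIF.
#'
#' @param design a [build_design()] result.
#' @return list of class `collinearity_diagnostics`: `vif` data.frame
#'   (regressor, vif, flag, max_abs_r, r_flag) and the `correlations` matrix.
#' @export
collinearity_diagnostics <- function(design) {
  stopifnot(inherits(design, "design_matrix"))
  ev <- design$matrix[, design$event_cols, drop = FALSE]
  if (ncol(ev) < 2)
    stop("need at least 2 event regressors for collinearity diagnostics",
         call. = FALSE)
  vif <- sapply(seq_len(ncol(ev)), function(j) {
    y <- ev[, j]
    X <- cbind(1, ev[, -j, drop = FALSE])
    fit <- stats::lm.fit(X, y)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  })
  r <- stats::cor(ev)
  max_r <- sapply(seq_len(ncol(ev)), function(j) max(abs(r[j, -j])))
  flag <- ifelse(!is.finite(vif) | vif >= 10, "high",
                 ifelse(vif > 5, "moderate", "none"))
  structure(list(
    vif = data.frame(regressor = colnames(ev), vif = vif, flag = flag,
                     max_abs_r = max_r, r_flag = max_r >= 0.90),
    correlations = r), class = "collinearity_diagnostics")
}

#' @export
print.collinearity_diagnostics <- function(x, ...) {
  print(x$vif, digits = 3)
  invisible(x)
}
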