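#' Specification for least-squares-separate deconvolution
#'
#' The target epoch determines which included-epoch set the stepwise rule
#' prescribes: recall-related deconvolution models recall events only,
#' encoding-related deconvolution models recall and encoding events, and
#' ITI-related deconvolution models all three; localizer deconvolution
#' targets the stimulus epoch. Supplying `included_epochs` that violate the
#' stepwise rule is a specification error.
#'
#' @param epoch target epoch: `"recall"`, `"encoding"`, `"iti"` or
#'   `"stimulus"`.
#' @param included_epochs epochs modelled in each per-trial GLM; defaults to
#'   the stepwise set for `epoch`.
#' @param smoothing_fwhm kernel applied to beta maps in [extract_roi()] (mm).
#' @param trial_filter optional predicate `function(events) -> logical`
#'   restricting which trials get a beta map (e.g. correct rejections only).
#' @param nuisance how the other trials' events are controlled: `"epoch"`
#'   (default) aggregates them into one regressor per included epoch, which
#'   keeps each per-trial GLM small and low-variance under noise but absorbs
#'   trial-by-trial amplitude variation only on average; `"trial"` gives
#'   every other event its own regressor, which recovers noise-free
#'   single-trial amplitudes exactly at the cost of a much larger model.
#' @return object of class `lss_spec`.
#' @export
lss_spec <- function(epoch = c("recall", "encoding", "iti", "stimulus"),
                     included_epochs = NULL, smoothing_fwhm = 6,
                     trial_filter = NULL, nuisance = c("epoch", "trial")) {
  epoch <- match.arg(epoch)
  nuisance <- match.arg(nuisance)
  stepwise <- list(recall = "recall",
                   encoding = c("recall", "encoding"),
                   iti = c("recall", "encoding", "iti"),
                   stimulus = "stimulus")
  if (is.null(included_epochs)) included_epochs <- stepwise[[epoch]]
  if (!setequal(included_epochs, stepwise[[epoch]]))
    stop("specification error: epoch '", epoch, "' requires included epochs {",
         paste(stepwise[[epoch]], collapse = ", "), "}", call. = FALSE)
  structure(list(epoch = epoch, included_epochs = included_epochs,
                 smoothing_fwhm = smoothing_fwhm,
                 trial_filter = trial_filter, nuisance = nuisance),
            class = "lss_spec")
}

#' Least-squares-separate single-trial deconvolution
#'
#' For each filtered trial, fits one GLM per run containing a dedicated
#' HRF-convolved regressor for that trial's target-epoch event, one nuisance
#' regressor per included epoch aggregating all other trials' events of that
#' epoch, the confound columns, a cosine drift set and an intercept; the
#' target regressor's coefficient is the trial's beta map. GLMs never cross
#' run boundaries. With a single trial in a run the scheme reduces exactly to
#' the ordinary single-regressor GLM.
#'
#' @param volumes a `bold_sim`, or a list of per-run [vol4d()] objects.
#' @param events event table covering all runs (required unless `volumes` is
#'   a `bold_sim`).
#' @param confounds optional list of per-run confound matrices.
#' @param spec an [lss_spec()].
#' @param drift_cutoff cosine drift high-pass cutoff (s), `NULL` to disable.
#' @return object of class `beta_series_maps`: `maps` (trials x voxels
#'   matrix), `trial_meta` (rows of `events` that received a map), `dims`,
#'   `voxel_mm`, `epoch`.
#' @export
lss_deconvolve <- function(volumes, events = NULL, confounds = NULL,
                           spec = lss_spec("recall"), drift_cutoff = 128) {
  if (inherits(volumes, "bold_sim")) {
    events <- events %||% volumes$ground_truth$schedule
    confounds <- confounds %||% volumes$ground_truth$confounds
    volumes <- volumes$runs
  }
  stopifnot(is.list(volumes), !is.null(events))
  onset_col <- paste0("onset_", spec$epoch)
  dur_col <- paste0("dur_", spec$epoch)
  if (spec$epoch == "stimulus" && !onset_col %in% names(events))
    stop("events lack a stimulus epoch", call. = FALSE)
  stopifnot(all(c(onset_col, dur_col) %in% names(events)))
  keep <- if (is.null(spec$trial_filter)) rep(TRUE, nrow(events))
          else spec$trial_filter(events)
  runs <- sort(unique(events$run))
  stopifnot(length(volumes) == length(runs))
  maps <- list(); meta_rows <- integer(0)
  dims <- NULL; voxel_mm <- 2.2
  for (ri in seq_along(runs)) {
    vol <- volumes[[ri]]
    dims <- spatial_dim(vol); voxel_mm <- vol$voxel_mm
    Y <- as_frame_matrix(vol)
    nf <- nrow(Y)
    frame_times <- (seq_len(nf) - 1) * vol$tr
    run_idx <- which(events$run == runs[ri])
    ev <- events[run_idx, , drop = FALSE]
    conf <- if (!is.null(confounds)) as.matrix(confounds[[ri]])
            else matrix(numeric(0), nf, 0)
    drift <- if (is.null(drift_cutoff)) matrix(numeric(0), nf, 0)
             else cosine_drift(frame_times, drift_cutoff)
    # one convolved regressor per event, computed once per run and reused
    # across the per-trial GLMs
    event_regs <- lapply(spec$included_epochs, function(ep) {
      oc <- paste0("onset_", ep); dc <- paste0("dur_", ep)
      if (!oc %in% names(ev)) return(NULL)
      cols <- vapply(seq_len(nrow(ev)), function(i) {
        if (is.na(ev[[oc]][i])) return(rep(NA_real_, nf))
        convolve_events(ev[[oc]][i], ev[[dc]][i], frame_times)
      }, numeric(nf))
      matrix(cols, nf, nrow(ev))
    })
    names(event_regs) <- spec$included_epochs
    event_regs <- Filter(Negate(is.null), event_regs)
    target_trials <- which(keep[run_idx])
    for (ti in target_trials) {
      if (is.na(ev[[onset_col]][ti])) {
        message("LSS: trial ", run_idx[ti], " lacks a ", spec$epoch,
                " event; skipped")
        next
      }
      target <- event_regs[[spec$epoch]][, ti]
      nuis <- lapply(names(event_regs), function(ep) {
        sel <- if (ep == spec$epoch) setdiff(seq_len(nrow(ev)), ti)
               else seq_len(nrow(ev))
        sel <- sel[!is.na(event_regs[[ep]][1, sel])]
        if (length(sel) == 0) return(NULL)
        cols <- event_regs[[ep]][, sel, drop = FALSE]
        if (spec$nuisance == "trial") cols else rowSums(cols)
      })
      nuis <- Filter(Negate(is.null), nuis)
      X <- cbind(target = target,
                 if (length(nuis)) do.call(cbind, nuis),
                 conf, drift, intercept = 1)
      fit <- stats::lm.fit(X, Y)
      maps[[length(maps) + 1]] <- fit$coefficients[1, ]
      meta_rows <- c(meta_rows, run_idx[ti])
    }
  }
  if (length(maps) == 0) stop("no trials survived the filter", call. = FALSE)
  structure(list(maps = do.call(rbind, maps),
                 trial_meta = events[meta_rows, , drop = FALSE],
                 dims = dims, voxel_mm = voxel_mm, epoch = spec$epoch),
            class = "beta_series_maps")
}

#' @export
print.beta_series_maps <- function(x, ...) {
  cat(sprintf("beta_series_maps (%s epoch): %d trial maps x %d voxels\n",
              x$epoch, nrow(x$maps), ncol(x$maps)))
  invisible(x)
}

#' Smooth beta maps and extract an ROI betaseries
#'
#' Each per-trial beta map is smoothed with a Gaussian kernel, then the
#' voxels of the (non-empty) mask are collected into a trials x voxels
#' matrix with the trial metadata joined.
#'
#' @param beta_maps a [lss_deconvolve()] result.
#' @param mask logical array (or integer index vector) of ROI voxels.
#' @param fwhm smoothing FWHM in mm (0 = no smoothing).
#' @return object of class `beta_series`: `matrix` (trials x mask voxels),
#'   `trial_meta`, `mask` (linear indices), `epoch`.
#' @export
extract_roi <- function(beta_maps, mask, fwhm = 6) {
  stopifnot(inherits(beta_maps, "beta_series_maps"))
  idx <- if (is.logical(mask) || is.array(mask)) which(as.vector(mask) != 0)
         else as.integer(mask)
  if (length(idx) == 0) stop("empty mask", call. = FALSE)
  M <- beta_maps$maps
  if (fwhm > 0 && !is.null(beta_maps$dims)) {
    M <- t(apply(M, 1, function(row)
      as.vector(smooth_volume(array(row, beta_maps$dims), fwhm,
                              beta_maps$voxel_mm))))
  }
  structure(list(matrix = M[, idx, drop = FALSE],
                 trial_meta = beta_maps$trial_meta,
                 mask = idx, epoch = beta_maps$epoch),
            class = "beta_series")
}

#' @export
print.beta_series <- function(x, ...) {
  cat(sprintf("beta_series (%s epoch): %d trials x %d voxels\n",
              x$epoch, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}
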