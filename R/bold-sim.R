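#' Multivoxel pattern specification for the simulated scan
#'
#' Defines the simulated volume geometry, a contiguous face-selective ROI
#' standing in for cytoarchitectonic area FG-4, the category patterns
#' expressed there, and how event amplitudes are modulated. The default grid
#' is 12 x 12 x 10 voxels at 2.2 mm isotropic with a 20-voxel ROI block. Face
#' information is expressed during the recall (face alone), encoding
#' (face + gabor) and rehearsal/ITI epochs with independently configurable
#' gains whose default ordering (1, 0.5, 0.15) encodes progressively weaker
#' face processing across those epochs. Association-task face amplitudes are
#' `base_amplitude + demand_effect * demand + success_effect * success`,
#' scaled by the epoch gain.
#'
#' @param grid_dim length-3 integer vector of volume dimensions.
#' @param roi integer vector of linear voxel indices; default a contiguous
#'   4 x 5 x 1 block.
#' @param face_pattern,house_pattern numeric vectors over `roi`; defaults are
#'   drawn from the seed with the face pattern elevated so most ROI voxels are
#'   face-preferring. Must be non-collinear.
#' @param base_amplitude BOLD units of a demand-free event.
#' @param demand_effect,success_effect amplitude increments for encoding
#'   demand = 1 and subsequent recall success = 1.
#' @param epoch_gains named multipliers for `recall`, `encoding`, `iti`.
#' @param voxel_mm isotropic voxel size (mm).
#' @param seed seed for the default patterns.
#' @return object of class `pattern_spec`.
#' @export
pattern_spec <- function(grid_dim = c(12, 12, 10), roi = NULL,
                         face_pattern = NULL, house_pattern = NULL,
                         base_amplitude = 1, demand_effect = 0.2,
                         success_effect = 0.1,
                         epoch_gains = c(recall = 1, encoding = 0.5,
                                         iti = 0.15),
                         voxel_mm = 2.2, seed = 1L) {
  stopifnot(length(grid_dim) == 3, all(grid_dim >= 1))
  if (is.null(roi)) {
    idx <- array(seq_len(prod(grid_dim)), dim = grid_dim)
    xs <- 5:min(8, grid_dim[1]); ys <- 5:min(9, grid_dim[2])
    zc <- min(5, grid_dim[3])
    roi <- as.vector(idx[xs, ys, zc])
  }
  stopifnot(all(roi >= 1), all(roi <= prod(grid_dim)))
  if (is.null(face_pattern) || is.null(house_pattern)) {
    pats <- with_seed(seed, list(
      face = 1 + 0.5 * stats::rnorm(length(roi)),
      house = 0.4 + 0.5 * stats::rnorm(length(roi))))
    if (is.null(face_pattern)) face_pattern <- pats$face
    if (is.null(house_pattern)) house_pattern <- pats$house
  }
  stopifnot(length(face_pattern) == length(roi),
            length(house_pattern) == length(roi))
  cs <- sum(face_pattern * house_pattern) /
    (sqrt(sum(face_pattern^2)) * sqrt(sum(house_pattern^2)))
  if (abs(cs) >= 1 - 1e-10)
    stop("face and house patterns must be non-collinear", call. = FALSE)
  stopifnot(all(c("recall", "encoding", "iti") %in% names(epoch_gains)))
  structure(list(grid_dim = grid_dim, roi = roi,
                 face_pattern = face_pattern, house_pattern = house_pattern,
                 base_amplitude = base_amplitude,
                 demand_effect = demand_effect,
                 success_effect = success_effect,
                 epoch_gains = epoch_gains, voxel_mm = voxel_mm),
            class = "pattern_spec")
}

#' Noise specification for the simulated scan
#'
#' Additive AR(1) Gaussian voxel noise plus seeded low-frequency drift and
#' smooth nuisance signals emulating motion/cardiac/respiratory confound
#' regressors (their construction from raw recordings is out of scope; only
#' their statistical footprint is emulated). The confound *signals* are
#' reproducible from the seed and returned in the ground truth so analyses
#' can include them as known nuisance regressors.
#'
#' @param sigma marginal noise SD (BOLD units).
#' @param ar_coefficient lag-1 autocorrelation in `[0, 1)`.
#' @param n_drift number of cosine drift terms expressed in the data.
#' @param n_confounds number of nuisance signal columns.
#' @param drift_sd,confound_sd SDs of per-voxel drift coefficients and
#'   confound loadings.
#' @param seed integer seed.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 1, ar_coefficient = 0.3, n_drift = 3,
                       n_confounds = 6, drift_sd = 0.3, confound_sd = 0.3,
                       seed = 1L) {
  stopifnot(sigma >= 0, ar_coefficient >= 0, ar_coefficient < 1,
            n_drift >= 0, n_confounds >= 0)
  structure(list(sigma = sigma, ar_coefficient = ar_coefficient,
                 n_drift = n_drift, n_confounds = n_confounds,
                 drift_sd = drift_sd, confound_sd = confound_sd,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

# smooth nuisance signal: AR(1) with high autocorrelation, unit marginal SD
smooth_signal <- function(n, rho = 0.95) {
  as.vector(stats::arima.sim(list(ar = rho), n = n,
                             sd = sqrt(1 - rho^2)))
}

ar1_noise <- function(n_frames, n_voxels, sigma, rho) {
  if (sigma == 0) return(matrix(0, n_frames, n_voxels))
  innov_sd <- sigma * sqrt(1 - rho^2)
  E <- matrix(stats::rnorm(n_frames * n_voxels, sd = innov_sd),
              n_frames, n_voxels)
  E[1, ] <- stats::rnorm(n_voxels, sd = sigma)
  if (rho > 0) for (t in 2:n_frames) E[t, ] <- rho * E[t - 1, ] + E[t, ]
  E
}

#' Simulate 4D BOLD volumes with embedded multivoxel patterns
#'
#' Forward model, per run: each event contributes its HRF-convolved boxcar
#' (identical convolution to [build_design()], so noise-free simulations are
#' exactly invertible by the matching GLM) times an amplitude times the
#' category pattern over the ROI, plus per-voxel drift, confound loadings and
#' AR(1) noise. For association-task trials, face information is expressed
#' during the recall, encoding and ITI (rehearsal) epochs with amplitude
#' `epoch_gain * (base + demand_effect * demand + success_effect * success)`;
#' for localizer trials the stimulus epoch expresses the face or house
#' pattern at `base_amplitude`. Confidence and feedback epochs carry no
#' pattern signal.
#'
#' @param schedule an association (with behavior) or localizer event table.
#' @param pattern a [pattern_spec()].
#' @param noise a [noise_spec()].
#' @param design the [task_design()] or [localizer_design()] that produced
#'   the schedule (supplies the TR).
#' @param n_frames optional frames per run (scalar or per-run vector);
#'   defaults to covering the last event plus 16 s. Errors if the schedule
#'   outlasts an explicit value.
#' @param trial_gain optional numeric vector (one value per schedule row)
#'   multiplying that trial's event amplitudes — used to plant known
#'   trial-by-trial amplitude variation for single-trial recovery studies.
#' @return object of class `bold_sim`: `runs` (list of [vol4d()], one per
#'   run) and `ground_truth` (per-event amplitudes, per-run confound
#'   matrices, the pattern spec, the schedule).
#' @export
simulate_bold <- function(schedule, pattern, noise, design, n_frames = NULL,
                          trial_gain = NULL) {
  tr <- design$tr
  if (is.null(trial_gain)) trial_gain <- rep(1, nrow(schedule))
  stopifnot(length(trial_gain) == nrow(schedule))
  localizer <- "onset_stimulus" %in% names(schedule)
  if (!localizer)
    stopifnot("accuracy" %in% names(schedule)) # behavior must be simulated
  fac <- if (!localizer) code_factors(schedule) else NULL
  runs <- sort(unique(schedule$run))
  n_vox <- prod(pattern$grid_dim)
  vols <- vector("list", length(runs))
  amp_rows <- list()
  confound_list <- vector("list", length(runs))
  with_seed(noise$seed, {
    for (ri in seq_along(runs)) {
      run_sel <- schedule$run == runs[ri]
      ev <- schedule[run_sel, , drop = FALSE]
      tg <- trial_gain[run_sel]
      fac_r <- if (!localizer) fac[run_sel, , drop = FALSE]
      last_off <- if (localizer) max(ev$onset_stimulus + ev$dur_stimulus)
                  else max(ev$onset_iti + ev$dur_iti)
      need <- ceiling((last_off + 16) / tr)
      nf <- if (is.null(n_frames)) need
            else if (length(n_frames) > 1) n_frames[ri] else n_frames
      if (nf < need)
        stop("duration error: schedule (", round(last_off, 1),
             " s) exceeds the requested scan of ", nf, " frames",
             call. = FALSE)
      frame_times <- (seq_len(nf) - 1) * tr
      Y <- matrix(0, nf, n_vox)
      add_event <- function(onset, dur, amplitude, pat) {
        r <- convolve_events(onset, dur, frame_times)
        Y[, pattern$roi] <<- Y[, pattern$roi] + outer(r, amplitude * pat)
      }
      if (localizer) {
        for (i in seq_len(nrow(ev))) {
          pat <- if (ev$category[i] == "face") pattern$face_pattern
                 else pattern$house_pattern
          a <- pattern$base_amplitude * tg[i]
          add_event(ev$onset_stimulus[i], ev$dur_stimulus[i], a, pat)
          amp_rows[[length(amp_rows) + 1]] <- data.frame(
            run = runs[ri], trial = ev$trial[i], epoch = "stimulus",
            amplitude = a)
        }
      } else {
        for (i in seq_len(nrow(ev))) {
          demand <- fac_r$demand[i]; success <- fac_r$success[i]
          mod <- tg[i] * (pattern$base_amplitude +
            pattern$demand_effect * (if (is.na(demand)) 0 else demand) +
            pattern$success_effect * (if (is.na(success)) 0 else success))
          for (ep in c("recall", "encoding", "iti")) {
            a <- pattern$epoch_gains[[ep]] * mod
            if (a == 0) next
            add_event(ev[[paste0("onset_", ep)]][i],
                      ev[[paste0("dur_", ep)]][i], a, pattern$face_pattern)
            amp_rows[[length(amp_rows) + 1]] <- data.frame(
              run = runs[ri], trial = ev$trial[i], epoch = ep, amplitude = a)
          }
        }
      }
      if (noise$n_confounds > 0) {
        C <- sapply(seq_len(noise$n_confounds), function(j) smooth_signal(nf))
        C <- matrix(C, nf, noise$n_confounds)
        colnames(C) <- paste0("confound_", seq_len(noise$n_confounds))
        load <- matrix(stats::rnorm(noise$n_confounds * n_vox,
                                    sd = noise$confound_sd),
                       noise$n_confounds, n_vox)
        Y <- Y + C %*% load
        confound_list[[ri]] <- C
      } else confound_list[[ri]] <- matrix(numeric(0), nf, 0)
      if (noise$n_drift > 0) {
        D <- cosine_drift(frame_times, cutoff = 2 * max(frame_times) /
                            noise$n_drift)
        D <- D[, seq_len(min(noise$n_drift, ncol(D))), drop = FALSE]
        coefs <- matrix(stats::rnorm(ncol(D) * n_vox, sd = noise$drift_sd),
                        ncol(D), n_vox)
        Y <- Y + D %*% coefs
      }
      Y <- Y + ar1_noise(nf, n_vox, noise$sigma, noise$ar_coefficient)
      vols[[ri]] <- vol4d(array(t(Y), dim = c(pattern$grid_dim, nf)),
                          tr = tr, voxel_mm = pattern$voxel_mm)
    }
  })
  amps <- if (length(amp_rows)) do.call(rbind, amp_rows) else
    data.frame(run = integer(), trial = integer(), epoch = character(),
               amplitude = numeric())
  structure(list(runs = vols,
                 ground_truth = list(amplitudes = amps,
                                     confounds = confound_list,
                                     pattern = pattern,
                                     schedule = schedule)),
            class = "bold_sim")
}

#' @export
print.bold_sim <- function(x, ...) {
  cat("bold_sim:", length(x$runs), "run(s)\n")
  for (v in x$runs) print(v)
  invisible(x)
}
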