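#' Write an event table as a BIDS-style long events TSV
#'
#' Association-task rows are expanded to one row per epoch event (trial_type
#' `recall`, `confidence`, `feedback`, `encoding`, `iti`); localizer rows
#' become one row per stimulus event (trial_type `stimulus_face` /
#' `stimulus_house`). Behavioral and schedule metadata ride along as extra
#' columns, so [read_events_tsv()] can reconstruct the wide per-trial table.
#'
#' @param events an event table from the schedule generators.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  if ("onset_stimulus" %in% names(events)) {
    long <- data.frame(onset = events$onset_stimulus,
                       duration = events$dur_stimulus,
                       trial_type = paste0("stimulus_", events$category),
                       run = events$run, trial = events$trial,
                       stimulus_id = events$stimulus_id,
                       gabor = events$gabor,
                       is_repetition = events$is_repetition)
    if ("pressed" %in% names(events)) long$pressed <- events$pressed
  } else {
    epochs <- c("recall", "confidence", "feedback", "encoding", "iti")
    long <- do.call(rbind, lapply(epochs, function(ep) {
      d <- data.frame(onset = events[[paste0("onset_", ep)]],
                      duration = events[[paste0("dur_", ep)]],
                      trial_type = ep,
                      run = events$run, trial = events$trial,
                      face_id = events$face_id,
                      presentation = events$presentation)
      if ("accuracy" %in% names(events)) {
        d$accuracy <- events$accuracy
        d$confidence <- events$confidence
      }
      d
    }))
    long <- long[order(long$run, long$onset), ]
  }
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events TSV back into a wide per-trial event table
#'
#' @param path a file written by [write_events_tsv()].
#' @return an `event_table` data.frame, one row per trial.
#' @export
read_events_tsv <- function(path) {
  long <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  if (any(startsWith(long$trial_type, "stimulus_"))) {
    out <- long
    out$category <- sub("^stimulus_", "", out$trial_type)
    out$onset_stimulus <- out$onset
    out$dur_stimulus <- out$duration
    out <- out[order(out$run, out$trial),
               setdiff(names(out), c("onset", "duration", "trial_type"))]
  } else {
    base_cols <- intersect(c("run", "trial", "face_id", "presentation",
                             "accuracy", "confidence"), names(long))
    first <- long[long$trial_type == "recall", base_cols, drop = FALSE]
    out <- first
    for (ep in c("recall", "confidence", "feedback", "encoding", "iti")) {
      sub <- long[long$trial_type == ep, c("run", "trial", "onset", "duration")]
      names(sub)[3:4] <- c(paste0("onset_", ep), paste0("dur_", ep))
      out <- merge(out, sub, by = c("run", "trial"), sort = FALSE)
    }
    out <- out[order(out$run, out$trial), ]
  }
  rownames(out) <- NULL
  class(out) <- c("event_table", "data.frame")
  out
}

#' Write / read a confound matrix as TSV
#'
#' @param confounds numeric matrix, one row per frame.
#' @param path file path.
#' @return `path` invisibly; the reader returns a numeric matrix.
#' @export
write_confounds_tsv <- function(confounds, path) {
  df <- as.data.frame(confounds)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_confounds_tsv
#' @export
read_confounds_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE))
}

#' Write / read a volume as NIfTI
#'
#' 4D [vol4d()] series store the TR in the NIfTI header's 4th pixdim slot;
#' 3D arrays (masks, stat maps) are written with the voxel size alone.
#'
#' @param vol a [vol4d()] or a 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_mm voxel size used when `vol` is a plain array.
#' @return `path` invisibly.
#' @export
write_nifti <- function(vol, path, voxel_mm = 2.2) {
  if (inherits(vol, "vol4d")) {
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- c(rep(vol$voxel_mm, 3), vol$tr)
  } else {
    img <- RNifti::asNifti(vol)
    RNifti::pixdim(img) <- rep(voxel_mm, length(dim(vol)))
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti
#' @param tr repetition time to attach when reading a 4D series; `NULL`
#'   takes it from the header.
#' @export
read_nifti_vol <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4) {
    pd <- RNifti::pixdim(img)
    vol4d(arr, tr = tr %||% pd[4], voxel_mm = pd[1])
  } else arr
}

#' Write an evidence or summary table as TSV
#'
#' @param x data.frame.
#' @param path file path.
#' @return `path` invisibly; the reader returns a data.frame.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

# Ground-truth JSON sidecar for a simulated participant
write_ground_truth_json <- function(gt, path) {
  obj <- list(amplitudes = gt$amplitudes,
              roi = gt$pattern$roi,
              face_pattern = gt$pattern$face_pattern,
              house_pattern = gt$pattern$house_pattern,
              grid_dim = gt$pattern$grid_dim,
              epoch_gains = as.list(gt$pattern$epoch_gains),
              base_amplitude = gt$pattern$base_amplitude,
              demand_effect = gt$pattern$demand_effect,
              success_effect = gt$pattern$success_effect)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

read_ground_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
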