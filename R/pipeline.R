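#' Assemble a pipeline run configuration
#'
#' All stage parameters in one serialisable object. Every stochastic stage
#' derives its seed deterministically from `master_seed` via
#' [derive_seed()], so a configuration fully determines the run. The
#' defaults are the study's task economy (5 runs x 8 faces x 4
#' presentations; 5 localizer runs of 16 trials) at the desk-scale volume
#' geometry.
#'
#' @param n_participants number of simulated participants (group stages
#'   need at least 3).
#' @param master_seed integer master seed.
#' @param output_root directory for all stage outputs.
#' @param design,localizer,behavior,pattern,noise named lists of overrides
#'   for [task_design()], [localizer_design()], [behavior_params()],
#'   [pattern_spec()] and [noise_spec()].
#' @param glm,group,lss,mvpa,link stage parameter lists (see Details in the
#'   package vignette).
#' @return object of class `run_config`.
#' @export
run_config <- function(n_participants = 6, master_seed = 1,
                       output_root = "memtrace_out",
                       design = list(), localizer = list(),
                       behavior = list(), pattern = list(), noise = list(),
                       glm = list(), group = list(), lss = list(),
                       mvpa = list(), link = list()) {
  merge_defaults <- function(user, defaults) {
    for (nm in names(user)) defaults[[nm]] <- user[[nm]]
    defaults
  }
  cfg <- list(
    n_participants = n_participants,
    master_seed = as.integer(master_seed),
    output_root = output_root,
    design = design, localizer = localizer, behavior = behavior,
    pattern = pattern, noise = noise,
    glm = merge_defaults(glm, list(drift_cutoff = 128)),
    group = merge_defaults(group, list(q = 0.05, min_extent = 5, fwhm = 8,
                                       n_perm = 1000)),
    lss = merge_defaults(lss, list(fwhm = 6)),
    mvpa = merge_defaults(mvpa, list(n_features = 14, svm_cost = 1)),
    link = merge_defaults(link, list(epochs = c("recall", "encoding", "iti"),
                                     wholebrain = FALSE)))
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return the path / the configuration.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Deterministic toy seven-network parcellation
#'
#' Slab parcellation along the z axis: the bottom and top slices are
#' unassigned (label 0) and interior slices cycle through labels 1-7. Stands
#' in, at desk scale, for a cortical seven-network parcellation; it is
#' synthetic and carries no anatomical meaning.
#'
#' @param grid_dim length-3 volume dimensions.
#' @return integer array with labels 0-7.
#' @export
toy_parcellation <- function(grid_dim = c(12, 12, 10)) {
  arr <- array(0L, grid_dim)
  nz <- grid_dim[3]
  for (z in seq_len(nz)) {
    lab <- if (z == 1 || z == nz) 0L else ((z - 2L) %% 7L) + 1L
    arr[, , z] <- lab
  }
  arr
}

# participant directory and instantiated specs for one configuration
cfg_specs <- function(config) {
  list(design = do.call(task_design, config$design),
       localizer = do.call(localizer_design, config$localizer),
       behavior = do.call(behavior_params, config$behavior),
       pattern = do.call(pattern_spec, config$pattern),
       noise = do.call(noise_spec, config$noise))
}

sub_dir <- function(root, p) file.path(root, sprintf("sub-%02d", p))

checksum_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  sums <- tools::md5sum(paths)
  stats::setNames(unname(sums), basename(paths))
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes, in order: `simulate` (schedules, behavior, BOLD, ground truth to
#' disk), `behavior` (learning/meta-memory/localizer summaries), `glm`
#' (first-level error-monitoring contrasts per participant), `group`
#' (second-level FDR + extent maps, conjunction, network overlap), `lss`
#' (single-trial betaseries for the localizer and the three memory epochs),
#' `mvpa` (decoding cross-validation, full face-evidence model, evidence
#' tables) and `link` (mixed-model linkage of evidence to demand/success).
#' Stages communicate exclusively through files under `output_root`; a
#' manifest with content checksums is updated after every stage, so two runs
#' of the same configuration produce identical manifests. A failing stage
#' halts the pipeline, naming itself, with the partial manifest persisted.
#'
#' @param config a [run_config()].
#' @param stages subset of stages to run (in pipeline order).
#' @return the manifest (invisibly), also written to
#'   `output_root/manifest.json`.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "behavior", "glm", "group",
                                    "lss", "mvpa", "link")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  root <- config$output_root
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(root, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else
      list(config = unclass(config), stages = list(),
           package_version = as.character(utils::packageVersion("memtrace")))
  manifest$config <- unclass(config)
  specs <- cfg_specs(config)
  for (stage in stages) {
    res <- tryCatch(
      do.call(paste0("stage_", stage), list(config, specs)),
      error = function(e) e)
    if (inherits(res, "error")) {
      jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                           digits = NA)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    manifest$stages[[stage]] <- list(
      seed = derive_seed(config$master_seed, stage),
      files = as.list(checksum_files(res)))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(manifest)
}

stage_simulate <- function(config, specs) {
  root <- config$output_root
  out <- character(0)
  parc_path <- file.path(root, "parcellation.nii")
  write_nifti(toy_parcellation(specs$pattern$grid_dim) + 0, parc_path,
              voxel_mm = specs$pattern$voxel_mm)
  out <- c(out, parc_path)
  for (p in seq_len(config$n_participants)) {
    pd <- sub_dir(root, p)
    dir.create(pd, showWarnings = FALSE, recursive = TRUE)
    sp <- simulate_participant(
      seed = derive_seed(config$master_seed, paste0("participant_", p)),
      design = specs$design, loc_design = specs$localizer,
      behavior = specs$behavior, pattern = specs$pattern,
      noise = specs$noise)
    files <- c(assoc_events = file.path(pd, "assoc_events.tsv"),
               loc_events = file.path(pd, "loc_events.tsv"),
               gt = file.path(pd, "ground_truth.json"),
               roi = file.path(pd, "roi_mask.nii"))
    write_events_tsv(sp$association$events, files["assoc_events"])
    write_events_tsv(sp$localizer$events, files["loc_events"])
    write_ground_truth_json(sp$association$bold$ground_truth, files["gt"])
    roi_arr <- array(0, specs$pattern$grid_dim)
    roi_arr[sp$pattern$roi] <- 1
    write_nifti(roi_arr, files["roi"], voxel_mm = specs$pattern$voxel_mm)
    for (task in c("assoc", "loc")) {
      sim <- if (task == "assoc") sp$association$bold else sp$localizer$bold
      for (r in seq_along(sim$runs)) {
        bp <- file.path(pd, sprintf("%s_bold_run-%d.nii", task, r))
        cp <- file.path(pd, sprintf("%s_confounds_run-%d.tsv", task, r))
        write_nifti(sim$runs[[r]], bp)
        write_confounds_tsv(sim$ground_truth$confounds[[r]], cp)
        files <- c(files, bp, cp)
      }
    }
    out <- c(out, files)
  }
  out
}

stage_behavior <- function(config, specs) {
  root <- config$output_root
  assoc <- do.call(rbind, lapply(seq_len(config$n_participants), function(p) {
    ev <- read_events_tsv(file.path(sub_dir(root, p), "assoc_events.tsv"))
    ev$participant <- sprintf("sub-%02d", p)
    ev
  }))
  learn <- score_learning(assoc)
  meta <- lapply(split(assoc, assoc$participant), meta_memory)
  loc <- lapply(seq_len(config$n_participants), function(p)
    read_events_tsv(file.path(sub_dir(root, p), "loc_events.tsv")))
  perfs <- vapply(loc, function(ev) {
    x <- score_localizer(ev, cohort_performances = c(0, 1))
    x$performance
  }, numeric(1))
  loc_scores <- lapply(loc, score_localizer, cohort_performances = perfs)
  summary <- data.frame(
    participant = sprintf("sub-%02d", seq_len(config$n_participants)),
    accuracy_pct = vapply(split(assoc, assoc$participant),
                          function(d) 100 * mean(d$accuracy), numeric(1)),
    d_prime = vapply(meta, `[[`, numeric(1), "d_prime"),
    d_bias = vapply(meta, `[[`, numeric(1), "d_bias"),
    loc_hit_rate = vapply(loc_scores, `[[`, numeric(1), "hit_rate"),
    loc_cr_rate = vapply(loc_scores, `[[`, numeric(1), "cr_rate"),
    loc_excluded = vapply(loc_scores, `[[`, logical(1), "excluded"))
  sfile <- file.path(root, "behavior_summary.tsv")
  write_table_tsv(summary, sfile)
  gfile <- file.path(root, "behavior_group.json")
  jsonlite::write_json(list(overall_pct = learn$overall_pct,
                            block_means_pct = as.list(learn$block_means_pct),
                            t = learn$t_test$t, p = learn$t_test$p,
                            anova_F = learn$anova$F, anova_p = learn$anova$p),
                       gfile, auto_unbox = TRUE, digits = NA)
  c(sfile, gfile)
}

# error-monitoring contrasts of the recall/confidence/feedback model
pipeline_contrasts <- list(
  failed_recall = c(recall_Error_ConfLow = 1, recall_Correct_ConfHigh = -1),
  low_confidence = c(confidence_low = 1, confidence_high = -1),
  negative_feedback = c(feedback_negative = 1, feedback_positive = -1))

stage_glm <- function(config, specs) {
  root <- config$output_root
  out <- character(0)
  for (p in seq_len(config$n_participants)) {
    pd <- sub_dir(root, p)
    ev <- read_events_tsv(file.path(pd, "assoc_events.tsv"))
    runs <- sort(unique(ev$run))
    effects <- list()
    for (r in runs) {
      vol <- read_nifti_vol(file.path(pd, sprintf("assoc_bold_run-%d.nii", r)))
      conf <- read_confounds_tsv(file.path(pd,
                                           sprintf("assoc_confounds_run-%d.tsv", r)))
      des <- suppressWarnings(
        build_design(ev[ev$run == r, ], conf, tr = vol$tr,
                     n_frames = dim(vol$data)[4],
                     variant = "recall_confidence_feedback",
                     drift_cutoff = config$glm$drift_cutoff))
      fit <- fit_glm(vol, des)
      for (cn in names(pipeline_contrasts)) {
        w <- pipeline_contrasts[[cn]]
        if (!all(names(w) %in% fit$columns)) next
        effects[[cn]] <- c(effects[[cn]], list(contrast(fit, w)$effect))
      }
    }
    for (cn in names(pipeline_contrasts)) {
      if (is.null(effects[[cn]]))
        stop("contrast ", cn, " estimable in no run for participant ", p)
      avg <- Reduce(`+`, effects[[cn]]) / length(effects[[cn]])
      fp <- file.path(pd, sprintf("contrast_%s.nii", cn))
      write_nifti(avg, fp, voxel_mm = specs$pattern$voxel_mm)
      out <- c(out, fp)
    }
  }
  out
}

stage_group <- function(config, specs) {
  root <- config$output_root
  if (config$n_participants < 3)
    stop("group inference requires at least 3 participants")
  parc <- read_nifti_vol(file.path(root, "parcellation.nii"))
  out <- character(0)
  thresholded <- list(); subject_maps <- list()
  for (cn in names(pipeline_contrasts)) {
    maps <- lapply(seq_len(config$n_participants), function(p)
      read_nifti_vol(file.path(sub_dir(root, p),
                               sprintf("contrast_%s.nii", cn))))
    grp <- second_level(maps, fwhm = config$group$fwhm,
                        voxel_mm = specs$pattern$voxel_mm)
    thr <- threshold_map(grp, q = config$group$q,
                         min_extent = config$group$min_extent,
                         voxel_mm = specs$pattern$voxel_mm)
    thresholded[[cn]] <- thr
    subject_maps[[cn]] <- grp$subject_maps
    zf <- file.path(root, sprintf("group_z_%s.nii", cn))
    sf <- file.path(root, sprintf("group_sig_%s.nii", cn))
    write_nifti(grp$z, zf, voxel_mm = specs$pattern$voxel_mm)
    write_nifti(thr$significant + 0, sf, voxel_mm = specs$pattern$voxel_mm)
    out <- c(out, zf, sf)
  }
  conj <- conjunction(thresholded, subject_maps,
                      n_perm = config$group$n_perm,
                      seed = derive_seed(config$master_seed, "conjunction"))
  cf <- file.path(root, "conjunction_mask.nii")
  write_nifti(conj$conjunction_mask + 0, cf,
              voxel_mm = specs$pattern$voxel_mm)
  overlap <- do.call(rbind, lapply(names(thresholded), function(cn) {
    fr <- suppressWarnings(network_overlap(thresholded[[cn]], parc))
    data.frame(contrast = cn, network = names(fr), fraction = unname(fr))
  }))
  of <- file.path(root, "network_overlap.tsv")
  write_table_tsv(overlap, of)
  c(out, cf, of)
}

stage_lss <- function(config, specs) {
  root <- config$output_root
  out <- character(0)
  for (p in seq_len(config$n_participants)) {
    pd <- sub_dir(root, p)
    loc_ev <- read_events_tsv(file.path(pd, "loc_events.tsv"))
    loc_vols <- lapply(sort(unique(loc_ev$run)), function(r)
      read_nifti_vol(file.path(pd, sprintf("loc_bold_run-%d.nii", r))))
    loc_conf <- lapply(sort(unique(loc_ev$run)), function(r)
      read_confounds_tsv(file.path(pd, sprintf("loc_confounds_run-%d.tsv", r))))
    cr_only <- function(ev) !ev$is_repetition & !ev$pressed
    loc_bm <- lss_deconvolve(loc_vols, loc_ev, loc_conf,
                             spec = lss_spec("stimulus",
                                             trial_filter = cr_only),
                             drift_cutoff = config$glm$drift_cutoff)
    files <- write_betaseries(loc_bm, pd, "loc_stimulus")
    out <- c(out, files)
    ev <- read_events_tsv(file.path(pd, "assoc_events.tsv"))
    vols <- lapply(sort(unique(ev$run)), function(r)
      read_nifti_vol(file.path(pd, sprintf("assoc_bold_run-%d.nii", r))))
    confs <- lapply(sort(unique(ev$run)), function(r)
      read_confounds_tsv(file.path(pd, sprintf("assoc_confounds_run-%d.tsv", r))))
    for (ep in config$link$epochs) {
      bm <- lss_deconvolve(vols, ev, confs, spec = lss_spec(ep),
                           drift_cutoff = config$glm$drift_cutoff)
      out <- c(out, write_betaseries(bm, pd, paste0("assoc_", ep)))
    }
  }
  out
}

write_betaseries <- function(bm, dir, label) {
  bf <- file.path(dir, sprintf("betaseries_%s.nii", label))
  mf <- file.path(dir, sprintf("betaseries_%s_meta.tsv", label))
  arr <- array(t(bm$maps), dim = c(bm$dims, nrow(bm$maps)))
  write_nifti(vol4d(arr, tr = 1, voxel_mm = bm$voxel_mm), bf)
  meta <- bm$trial_meta
  meta$beta_index <- seq_len(nrow(meta))
  write_table_tsv(meta, mf)
  c(bf, mf)
}

read_betaseries <- function(dir, label, epoch) {
  vol <- read_nifti_vol(file.path(dir, sprintf("betaseries_%s.nii", label)))
  meta <- read_table_tsv(file.path(dir,
                                   sprintf("betaseries_%s_meta.tsv", label)))
  structure(list(maps = as_frame_matrix(vol), trial_meta = meta,
                 dims = spatial_dim(vol), voxel_mm = vol$voxel_mm,
                 epoch = epoch),
            class = "beta_series_maps")
}

stage_mvpa <- function(config, specs) {
  root <- config$output_root
  cfg <- mvpa_config(n_features = config$mvpa$n_features,
                     svm_cost = config$mvpa$svm_cost,
                     seed = derive_seed(config$master_seed, "mvpa"))
  cv_rows <- list(); evidence <- list()
  out <- character(0)
  for (p in seq_len(config$n_participants)) {
    pd <- sub_dir(root, p)
    roi <- read_nifti_vol(file.path(pd, "roi_mask.nii"))
    loc_bm <- read_betaseries(pd, "loc_stimulus", "stimulus")
    series <- extract_roi(loc_bm, roi, fwhm = config$lss$fwhm)
    cv <- cross_validate(series, cfg)
    cv_rows[[p]] <- data.frame(participant = sprintf("sub-%02d", p),
                               balanced_accuracy = cv$mean_balanced_accuracy,
                               class_difference = cv$mean_class_difference)
    model <- fit_full_model(series, cfg)
    mfile <- file.path(pd, "face_evidence_model.json")
    save_evidence_model(model, mfile)
    out <- c(out, mfile)
    for (ep in config$link$epochs) {
      bm <- read_betaseries(pd, paste0("assoc_", ep), ep)
      es <- extract_roi(bm, roi, fwhm = config$lss$fwhm)
      evidence[[length(evidence) + 1]] <-
        predict_evidence(model, es, epoch = ep,
                         participant = sprintf("sub-%02d", p))
    }
  }
  cv_file <- file.path(root, "mvpa_cv.tsv")
  ev_file <- file.path(root, "evidence.tsv")
  write_table_tsv(do.call(rbind, cv_rows), cv_file)
  write_table_tsv(do.call(rbind, evidence), ev_file)
  out <- c(out, cv_file, ev_file)
  if (config$n_participants >= 5) {
    val <- validate_probability_measure(do.call(rbind, evidence))
    vf <- file.path(root, "probability_validity.tsv")
    write_table_tsv(val, vf)
    out <- c(out, vf)
  }
  out
}

stage_link <- function(config, specs) {
  root <- config$output_root
  if (config$n_participants < 2)
    stop("mixed-model linkage requires at least 2 participants")
  evidence <- read_table_tsv(file.path(root, "evidence.tsv"))
  fac_all <- do.call(rbind, lapply(seq_len(config$n_participants),
                                   function(p) {
    ev <- read_events_tsv(file.path(sub_dir(root, p), "assoc_events.tsv"))
    fac <- code_factors(ev)
    fac$trial_id <- seq_len(nrow(fac))
    fac$participant <- sprintf("sub-%02d", p)
    fac
  }))
  merged <- merge(evidence, fac_all, by = c("participant", "trial_id"))
  rows <- list(); out <- character(0)
  for (ep in config$link$epochs) {
    d <- merged[merged$epoch == ep & merged$included, ]
    fit <- fit_mixed_model(d, epoch = ep)
    co <- fit$coefficients
    co$epoch <- ep
    co$method <- fit$method
    rows[[ep]] <- co
  }
  lf <- file.path(root, "link_coefficients.tsv")
  write_table_tsv(do.call(rbind, rows), lf)
  out <- c(out, lf)
  if (isTRUE(config$link$wholebrain)) {
    ep <- config$link$epochs[[1]]
    beta_list <- list(); ev_list <- list()
    for (p in seq_len(config$n_participants)) {
      bm <- read_betaseries(sub_dir(root, p), paste0("assoc_", ep), ep)
      beta_list[[p]] <- bm$maps
      ev_list[[p]] <- evidence[evidence$participant == sprintf("sub-%02d", p) &
                                 evidence$epoch == ep, ]
    }
    wb <- wholebrain_evidence_regression(
      lapply(beta_list, function(m) m),
      ev_list, fwhm = config$group$fwhm,
      voxel_mm = specs$pattern$voxel_mm)
    dims <- specs$pattern$grid_dim
    wf <- file.path(root, sprintf("evidence_group_z_%s.nii", ep))
    write_nifti(array(wb$group$z, dims), wf,
                voxel_mm = specs$pattern$voxel_mm)
    out <- c(out, wf)
  }
  out
}
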