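#' Simulate one participant's full session
#'
#' Generates the association-task schedule with behavior and the localizer
#' schedule with button presses, then the BOLD volumes for both tasks, all
#' from seeds derived deterministically from `seed`. Each participant gets
#' their own multivoxel face/house patterns (drawn from the derived seed)
#' over the shared ROI, mirroring participant-specific FFA topography.
#'
#' @param seed integer participant seed.
#' @param design association [task_design()].
#' @param loc_design [localizer_design()].
#' @param behavior [behavior_params()] (its seed field is overridden by a
#'   derived seed).
#' @param pattern a [pattern_spec()] template; patterns are redrawn per
#'   participant unless `shared_pattern = TRUE`.
#' @param noise a [noise_spec()] template (seed overridden).
#' @param shared_pattern reuse `pattern` exactly instead of redrawing.
#' @return list with `association` (schedule + `bold_sim`) and `localizer`
#'   components plus the specs used.
#' @export
simulate_participant <- function(seed, design = task_design(),
                                 loc_design = localizer_design(),
                                 behavior = behavior_params(),
                                 pattern = pattern_spec(),
                                 noise = noise_spec(),
                                 shared_pattern = FALSE) {
  pat <- if (shared_pattern) pattern else
    pattern_spec(grid_dim = pattern$grid_dim,
                 base_amplitude = pattern$base_amplitude,
                 demand_effect = pattern$demand_effect,
                 success_effect = pattern$success_effect,
                 epoch_gains = pattern$epoch_gains,
                 voxel_mm = pattern$voxel_mm,
                 seed = derive_seed(seed, "pattern"))
  assoc_sched <- generate_association_schedule(design,
                                               seed = derive_seed(seed, "assoc_schedule"))
  assoc_beh <- simulate_behavior(assoc_sched, behavior_params(
    learning_rate = behavior$learning_rate,
    guess_prob = behavior$guess_prob,
    conf_sensitivity = behavior$conf_sensitivity,
    conf_specificity = behavior$conf_specificity,
    seed = derive_seed(seed, "assoc_behavior")))
  loc_sched <- generate_localizer_schedule(loc_design,
                                           seed = derive_seed(seed, "loc_schedule"))
  loc_beh <- simulate_localizer_behavior(loc_sched,
                                         seed = derive_seed(seed, "loc_behavior"))
  assoc_noise <- noise_spec(sigma = noise$sigma,
                            ar_coefficient = noise$ar_coefficient,
                            n_drift = noise$n_drift,
                            n_confounds = noise$n_confounds,
                            drift_sd = noise$drift_sd,
                            confound_sd = noise$confound_sd,
                            seed = derive_seed(seed, "assoc_bold"))
  loc_noise <- noise_spec(sigma = noise$sigma,
                          ar_coefficient = noise$ar_coefficient,
                          n_drift = noise$n_drift,
                          n_confounds = noise$n_confounds,
                          drift_sd = noise$drift_sd,
                          confound_sd = noise$confound_sd,
                          seed = derive_seed(seed, "loc_bold"))
  list(association = list(events = assoc_beh,
                          bold = simulate_bold(assoc_beh, pat, assoc_noise,
                                               design)),
       localizer = list(events = loc_beh,
                        bold = simulate_bold(loc_beh, pat, loc_noise,
                                             loc_design)),
       pattern = pat, seed = seed)
}
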