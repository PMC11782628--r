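# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

noise_free <- function(seed = 1L) {
  noise_spec(sigma = 0, n_drift = 0, n_confounds = 0, seed = seed)
}

cr_only <- function(ev) !ev$is_repetition & !ev$pressed

# localizer participant at the study's noise level, with the derived
# correct-rejection betaseries over the ROI (used by the MVPA tests)
localizer_fixture <- function() {
  fixture("localizer", function() {
    sp <- simulate_participant(42)
    bm <- lss_deconvolve(sp$localizer$bold,
                         spec = lss_spec("stimulus", trial_filter = cr_only))
    series <- extract_roi(bm, sp$pattern$roi, fwhm = 6)
    list(sp = sp, beta_maps = bm, series = series)
  })
}

# low-noise localizer whose planted patterns are linearly separable
separable_fixture <- function() {
  fixture("separable", function() {
    ld <- localizer_design()
    sched <- simulate_localizer_behavior(
      generate_localizer_schedule(ld, seed = 11), seed = 12)
    pat <- pattern_spec(seed = 5)
    sim <- simulate_bold(sched, pat,
                         noise_spec(sigma = 0.05, ar_coefficient = 0,
                                    n_drift = 0, n_confounds = 0, seed = 3),
                         ld)
    bm <- lss_deconvolve(sim, spec = lss_spec("stimulus",
                                              trial_filter = cr_only))
    list(pattern = pat, series = extract_roi(bm, pat$roi, fwhm = 6))
  })
}
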