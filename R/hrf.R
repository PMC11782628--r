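#' Glover double-gamma hemodynamic response function
#'
#' Difference of two gamma densities with the canonical response peak at
#' 5.2 s, undershoot peak at 10.8 s, undershoot ratio 0.35 and 32 s support,
#' normalised to unit peak. The same function drives both the forward BOLD
#' simulation and design-matrix construction, so noise-free simulations invert
#' exactly.
#'
#' @param t numeric vector of times (seconds, >= 0 contributes).
#' @param peak_delay response peak time (s).
#' @param undershoot_delay undershoot peak time (s).
#' @param ratio undershoot amplitude relative to the peak.
#' @param dispersion gamma dispersion (s).
#' @return numeric vector, HRF evaluated at `t`.
#' @export
glover_hrf <- function(t, peak_delay = 5.2, undershoot_delay = 10.8,
                       ratio = 0.35, dispersion = 0.9) {
  h <- stats::dgamma(t, shape = peak_delay / dispersion + 1, scale = dispersion) -
    ratio * stats::dgamma(t, shape = undershoot_delay / dispersion + 1,
                          scale = dispersion)
  h[t < 0] <- 0
  # normalise on a fine reference grid so scaling is independent of `t`
  ref <- seq(0, 32, by = 0.01)
  peak <- max(stats::dgamma(ref, shape = peak_delay / dispersion + 1,
                            scale = dispersion) -
                ratio * stats::dgamma(ref, shape = undershoot_delay / dispersion + 1,
                                      scale = dispersion))
  h / peak
}

# Convolve event boxcars with the HRF on an oversampled grid and sample at
# frame times. Deterministic; shared by simulate_bold() and build_design().
#
# onsets/durations: seconds; frame_times: seconds; amplitudes: per-event gain.
convolve_events <- function(onsets, durations, frame_times,
                            amplitudes = NULL, dt = 0.1, hrf_length = 32) {
  if (length(onsets) == 0) return(numeric(length(frame_times)))
  if (is.null(amplitudes)) amplitudes <- rep(1, length(onsets))
  stopifnot(length(durations) %in% c(1L, length(onsets)),
            length(amplitudes) == length(onsets))
  durations <- rep_len(durations, length(onsets))
  t_max <- max(frame_times) + dt
  n_fine <- ceiling(t_max / dt) + 1L
  fine <- numeric(n_fine)
  for (i in seq_along(onsets)) {
    a <- floor(onsets[i] / dt) + 1L
    b <- ceiling((onsets[i] + durations[i]) / dt)
    b <- max(b, a)
    if (a > n_fine) next
    b <- min(b, n_fine)
    fine[a:b] <- fine[a:b] + amplitudes[i]
  }
  kern <- glover_hrf(seq(0, hrf_length, by = dt))
  conv <- stats::convolve(fine, rev(kern), type = "open")[seq_len(n_fine)] * dt
  idx <- pmin(pmax(round(frame_times / dt) + 1L, 1L), n_fine)
  conv[idx]
}
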