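---
title: "memtrace: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{memtrace: models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the generative model behind the synthetic data, the estimators applied to
it, the parameters that matter, and the places where a design decision was
genuinely open and had to be made. The companion README shows the pipeline
in action; here we explain why each piece looks the way it does.

## 1. The task economy and its simulation

The association task couples each face with one of eight gabor-patch
orientations. A trial runs through recall (the face alone), a confidence
report, feedback, and a re-encoding display, separated by a fixation
interval jittered uniformly on 2.5–6 s. Five runs of eight new faces, each
presented four times with same-face gaps of 2–15 trials, give 160 trials;
since first presentations are necessarily guesses, at most 120 trials can
draw on memory. The localizer shows faces and houses in a 1-back design: 16
trials per run (2 faces + 2 houses × 4), of which exactly two directly
repeat the preceding stimulus/gabor pair.

`generate_association_schedule()` sequences faces by constrained sequential
sampling (a face whose gap is about to exceed the maximum is forced; a face
re-appearing too soon is barred) with bounded restarts; an unsatisfiable
design raises a `schedule-infeasible` error naming the violated constraint.
The study-protocol constraints (counts, gap bounds, jitter bounds,
TR = 2 s) are the package defaults. Two timing choices were open:

* **Self-paced phase durations.** Recall and confidence are self-paced in
  the real task. We fix stand-ins of 2.0 s (face onset plus the gabor
  choice) and 1.0 s; feedback (0.8 s after a 0.2 s delay) and encoding
  (1.5 s) use the stated durations. Onsets follow in presentation order.
* **The ITI jitter distribution** is not specified beyond its bounds; we
  use the uniform distribution, the standard choice for jitter efficiency.
* **The rehearsal ("ITI") epoch** of a trial is the jittered interval
  *after* its encoding display — that is the window in which rehearsal of
  the just-seen association can occur.

## 2. Simulated behavior

Accuracy follows a logistic learning curve in presentation number $k$:

$$\Pr(\text{correct}) = \operatorname{logit}^{-1}\!\big(\operatorname{logit}(p_0) + \lambda\,(k-1)\big),
\qquad p_0 = 1/8 .$$

The default rate $\lambda = 1.7622$ is the analytic (uniroot) solution that
makes the design-mean accuracy over four presentations equal 59.35%, the
level this task is known to produce; it is calibrated once, in closed form,
not fitted to any simulation. Confidence is high with probability 0.8014 on
correct trials and low with probability 0.7622 on errors — the observed
meta-memory rates. The generator reproduces the qualitative structure of
real learning (monotone block-wise improvement, informative confidence); it
does *not* model per-face difficulty, fatigue, response times, or
interference between faces.

## 3. The BOLD forward model

Each event contributes an HRF-convolved boxcar times an amplitude times a
spatial pattern. The HRF is the Glover double-gamma (response peak 5.2 s,
undershoot peak 10.8 s, undershoot ratio 0.35, 32 s support, unit peak); the
same convolution routine (0.1 s oversampled grid, frame sampling) is used by
the simulator and by `build_design()`, which is what makes noise-free
simulations exactly invertible — a property the tests exploit as an oracle.

The volume is a 12 × 12 × 10 grid of 2.2 mm isotropic voxels — the study's
voxel size at desk scale — with a contiguous 20-voxel ROI standing in for
the face-selective mid-fusiform region (FG-4/FFA). Face information is
expressed at recall (gain 1), encoding (gain 0.5) and the rehearsal ITI
(gain 0.15): independently configurable gains whose decreasing defaults
encode the expectation that the face is fully present at recall, shares the
encoding display with the gabor, and is at best rehearsed during fixation.
Association-task amplitudes are

$$a = g_{\text{epoch}}\,\big(\text{base} + \beta_d\,\text{demand} + \beta_s\,\text{success}\big),$$

with defaults $\beta_d = 0.2$, $\beta_s = 0.1$ in BOLD units on base 1 —
moderate modulations of the kind event-related designs are powered for.
Noise is AR(1) Gaussian (marginal SD 1, lag-1 coefficient 0.3) plus cosine
drift and six smooth nuisance signals with random voxel loadings, emulating
the statistical footprint of motion/cardiac/respiratory confounds; the
nuisance *signals* are returned as ground truth so analyses can include
them as known regressors, exactly as fMRIPrep-style confound tables would
be. AR(1) is the minimal noise model under which single-trial estimators
behave non-trivially; real physiological noise is structured (spatially
correlated, non-stationary) in ways this generator does not attempt.
Passing tests on these data therefore demonstrate correctness of the
estimators under the stated model, not robustness to real-scanner artifacts.

## 4. First-level GLM

Plain voxelwise OLS with residual df = frames − rank. No prewhitening: the
estimator stays unbiased under AR(1) noise (a property the tests check by
simulation), only its variance is mildly misstated; AR(1) prewhitening is a
natural extension point. Condition regressors follow the study's two model
variants — recall/confidence/feedback, and recall/confidence/encoding with
encoding split by the (current, next) recall transition; feedback is
excluded there because it is temporally adjacent to and redundant with
encoding. Drift is a cosine basis with a 128 s high-pass cutoff — the conventional default; the protocol calls for a cosine drift
model but leaves the cutoff open. Empty conditions are dropped with a warning and contrasts that
reference them fail loudly. t statistics map to z by matching two-sided
tail probabilities on the log scale, which survives |t| far beyond double
tail underflow; zero-variance cases are capped at a large finite statistic
rather than returned as infinities.

## 5. Group inference

Participant contrast maps are smoothed (8 mm FWHM separable Gaussian with
edge renormalisation, so a constant map is a fixed point and `fwhm = 0` is
the identity), then tested voxelwise with a one-sample t against zero.
Thresholding is Benjamini–Hochberg at q < 0.05 over the analysis mask with
two-sided p-values, followed by removal of clusters below five voxels under
face (6-neighbour) connectivity — 53.24 mm³ at this voxel size. The
conjunction is the intersection of the thresholded significant sets; in
addition the voxelwise minimum statistic across contrasts is tested against
a sign-flip permutation null (participant-level random sign flips applied
identically to all contrasts, valid under a symmetric null; the
max-over-voxels distribution of the min statistic gives familywise p <
0.05). The permutation scheme was an open choice — the protocol asks only for
random permutations — and sign flipping is the standard construction
compatible with one-sample second-level tests. The null is computed on the
t scale and converted to z only for reporting; the two are monotone at
fixed df, so p-values are unchanged and the permutation loop stays cheap.
Fewer than 100 permutations are refused as unstable.

## 6. Least-squares-separate betaseries

For each target trial, one GLM per run contains the trial's target-epoch
regressor, nuisance regressors for the other events, confounds, drift and
an intercept; the target coefficient is the trial's beta. Epoch inclusion
is stepwise (recall; recall + encoding; all three) so that each
deconvolution controls exactly the epochs estimated before it. Two open
choices:

* **Smoothing order.** Beta maps are smoothed (6 mm) *after* deconvolution,
  before ROI extraction, following the stated order of operations; the
  `fwhm` argument makes the choice explicit and reversible.
* **Nuisance aggregation.** `lss_spec(nuisance = "epoch")` (default)
  aggregates all other trials of an epoch into one regressor — the
  low-variance, condition-wise control used by the univariate models, and
  the classic least-squares-separate form. Its known cost is that
  trial-by-trial amplitude *variation* in neighbouring trials is absorbed
  only on average, which biases noise-free recovery (correlations around
  0.95–0.98 at this trial pacing, through the 32 s HRF). For exact
  single-trial recovery the `"trial"` variant gives every other event its
  own regressor; in noise-free data the target amplitudes are then
  recovered to machine precision, and the recovery tests use it as the
  correctly-specified reference. Under realistic noise the aggregated
  default is the estimator of choice: the per-trial variant's design (≈ 100
  columns per run here) trades bias for much higher variance.

## 7. Cross-task decoding

Within leave-one-run-out cross-validation, a per-feature z-scaler and the
univariate feature selection are fit on the training runs only. Selection
keeps the 14 voxels with the strongest *positive* one-way F effects —
face-preferring voxels, as an FFA-like population should be; when fewer
than 14 voxels are face-preferring (possible under label permutation, where
smoothing leaves few independent directions in a small ROI) the remaining
slots are filled by F rank so permutation nulls remain well defined. The
classifier is a balanced, L2-regularised linear SVM (C = 1, class weights
inverse to class frequency) with Platt-scaled probabilities; libsvm's
internal cross-validation fits the sigmoid and is seeded for
reproducibility. Balanced accuracy averages the face and house recalls
(the open convention; it equals accuracy on balanced test sets). The full
model freezes the scaler, the selected features and the SVM as plain
numbers — weights, offset and sigmoid coefficients — so prediction is a
dot product and a logistic, models serialise to JSON (doubles as
17-significant-digit strings), and a reloaded model is bit-identical.
Probabilities at exactly 0.5 classify as face, an arbitrary documented
tie-break. With 70 correct-rejection training trials and 14 features the
samples-per-feature ratio is 5.

## 8. Evidence linkage

Transitions pair each trial's accuracy with the accuracy on the *next*
presentation of the same face: encoding demand is 0 for CorrectCorrect and
1 for ErrorError/ErrorCorrect; subsequent recall success is 0 for
ErrorError and 1 for ErrorCorrect/CorrectCorrect; CorrectError trials and
last presentations are excluded. The linkage model is

$$p_{it} = \beta_0 + \beta_d\,\text{demand}_{it} + \beta_s\,\text{success}_{it} + u_i + \varepsilon_{it}, \qquad u_i \sim \mathcal N(0, \tau^2),$$

fit by REML with Wald z inference, so coefficients read directly as
probability-scale increments. A random intercept is the stated grouping
structure ("participant as group factor"); random slopes are out of scope.
Singular random-effects fits fall back to OLS with participant-clustered
robust (CR0) standard errors, and the result records the downgrade. The
control variant refits success on the demand trials only
(ErrorError/ErrorCorrect), guarding against the effect being carried by
CorrectCorrect trials. In the whole-brain regression the evidence regressor
is centered within participant — an open choice; without centering the intercept leaks into the slope map; slopes then go to the
standard second level.

`simulate_evidence()` generates data directly under this linkage model
(base 0.4, participant SD 0.05, trial SD 0.15, clipped to [0, 1]). The
defaults give single-study Wald z values of the size such designs report,
and clipping is active on well under 1% of trials, so the estimator is
essentially correctly specified. Parameter-recovery studies inject the
probability-scale increments 0.04 and 0.015 there, because those truths are
defined on the probability scale; the BOLD chain maps amplitude effects to
probability effects through the classifier's nonlinearity, so it can only
be checked qualitatively (sign and epoch ordering), which the end-to-end
tests do.

## 9. Meta-memory and localizer scoring conventions

Meta-memory uses the equal-variance signal-detection form on
confidence-conditional rates: hit = P(high | correct), fa = P(high |
error), d′ = z(hit) − z(fa). The bias measure is the criterion
c = −(z(hit) + z(fa))/2 and is labelled as such — its zero point (no
tendency toward high or low confidence) matches the reported near-zero
bias convention. Rates of exactly 0 or 1 are adjusted by one trial's
proportion (1/n of the relevant count) before the normal quantile. The
localizer performance scalar is the mean of hit rate and correct-rejection
rate — performance is judged on hit and correct-rejection rates without a
prescribed combination rule, and the unweighted mean
treats both error types symmetrically. Exclusion is strict:
performance < cohort mean − 2 SD.

## 10. Problem sizes in the test suite

The suite validates calibration properties at sizes chosen to keep the
whole run at a few minutes on one CPU while leaving Monte-Carlo error well
below the tested margins: 500 null replicates for FDR familywise
calibration and 200 for the conjunction null (500 sign flips each, 12
participants, the full 12 × 12 × 10 grid), 200 label permutations for
decoding chance, 100 replicate 28-participant studies for mixed-model CI
coverage, and 400 simulated cohorts for behavioral calibration. The
acceptance script uses the same sizes and derives every stream from its
`--seed`.

## 11. Known limitations

Simulated noise is spatially white given the confound loadings; no
spatial autocorrelation beyond smoothing is modelled, so cluster-extent
behavior on real data will differ. OLS without prewhitening understates
first-level variance under autocorrelation (group inference, which uses
only per-participant point estimates, is unaffected). The toy seven-network
parcellation is synthetic slab labelling with no anatomical meaning.
Response times, gabor-orientation decoding and hierarchical meta-d′ are out
of scope.
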