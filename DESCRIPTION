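Package: memtrace
Title: Error-Driven Memory Representation Analysis for Simulated fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for studying how memory
    errors upregulate stimulus-category representations in event-related fMRI.
    Generates feedback-based association-learning and 1-back localizer task
    schedules, simulated behavior, and 4D BOLD volumes with known multivoxel
    ground truth; fits first-level GLMs with Glover-HRF regressors, contrasts
    and collinearity diagnostics; performs second-level inference with FDR and
    cluster-extent thresholding, min-statistic conjunction against a sign-flip
    permutation null, and seven-network overlap quantification; estimates
    single-trial betaseries by least-squares-separate deconvolution with
    stepwise epoch inclusion; trains a Platt-calibrated linear support vector
    machine on localizer trials and cross-classifies face-processing evidence
    onto memory epochs; and links trial-level decoded evidence to encoding
    demand and subsequent recall success in a linear mixed model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    e1071,
    lme4,
    sandwich,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
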