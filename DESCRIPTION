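Package: retromem
Title: Trial-Specific Reactivation and Connectivity Analysis for
    Emotion-Modulated Retroactive Memory Enhancement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sensory-preconditioning fMRI experiments in
    which emotional learning retroactively enhances memory for previously
    learnt neutral associations. Implements trial-level pattern-similarity
    (reinstatement) measures with Fisher-transformed Pearson correlations,
    canonical-HRF GLM estimation of trial and condition t-patterns,
    searchlight mapping, generalized psychophysiological interaction (gPPI)
    connectivity, resting-state seed connectivity with difference-map group
    regression, balanced k-fold cross-validated prediction with a
    permutation null, Steiger's test for dependent non-overlapping
    correlations, a two-mediator serial path model with bias-corrected
    bootstrap inference, and the bespoke behavioural statistics
    (position-dependent chance level, confidence and vividness binning,
    repeated-measures ANOVA via within-subject contrasts, d_av effect
    sizes). A synthetic-data generator emulates the two-phase 72-pair
    design, condition-dependent reinstatement, seed-target coupling and
    reinstatement-linked behaviour so every stage is testable end to end
    without any imaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    optparse,
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
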