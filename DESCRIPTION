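Package: alphanfb
Title: Simulation and Group Analysis of Alpha-Desynchronizing EEG Neurofeedback Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse a double-blind, sham-controlled EEG
    neurofeedback trial targeting down-regulation of the alpha rhythm (8-12 Hz)
    in post-traumatic stress disorder. Provides generators for synthetic
    resting-state EEG with a 1/f aperiodic background, band-limited oscillators
    and a group-dependent anterior alpha deficit; a two-state homeostatic
    "plant" model of session alpha amplitude; offline preprocessing (common
    average reference, zero-phase band-pass filtering, fixed-length epoching and
    z-score based artifact rejection); Welch spectral estimation with absolute
    and relative band power; a toy spherical forward model with an sLORETA
    minimum-norm inverse for source-space relative power maps; a closed-loop
    neurofeedback controller with percentile reward-threshold calibration,
    within-session adaptation and yoked sham replay; expectation-maximization
    imputation of missing sessions; and group statistics (Monte-Carlo
    permutation tests, Benjamini-Hochberg false discovery rate, conjunction
    masks, split-plot repeated-measures ANOVA with Greenhouse-Geisser
    correction, paired effect sizes and clinical outcome arithmetic), plus an
    end-to-end trial pipeline. EDF, CSV, JSON and YAML interchange supported.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
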