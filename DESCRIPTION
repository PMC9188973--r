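Package: specfmri
Title: Specification-Curve Multiverse Analysis of Task fMRI Amygdala-mPFC Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multiverse (specification-curve) analysis of task-evoked
    amygdala reactivity and amygdala-mPFC functional connectivity in accelerated
    longitudinal cohorts. Implements scan-level GLM estimation from region-of-interest
    BOLD timeseries (double/single-gamma HRF convolution, motion-expansion nuisance
    sets, discrete-cosine high-pass bases, framewise-displacement censoring, AR(1)
    prewhitening), least-squares-separate single-trial betas with within-scan
    trial-dynamics statistics, generalized psychophysiological interaction (gPPI)
    connectivity with an optional ridge deconvolution step, beta-series correlation,
    multilevel longitudinal age-trajectory models (fast frequentist via lme4 and
    Bayesian MCMC via JAGS, with within/between-participant age decomposition and
    robust variants), specification-grid enumeration and execution with
    evidence-proportion curves and decision-point meta-regression, and test-retest
    reliability via variance-decomposition intraclass correlations. A seeded
    synthetic-data generator emulates the study design (event-related emotional-face
    task, 1-3 scans per participant across ages 4-22) with known generative
    parameters so that every stage has a parameter-recovery oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    withr,
    yaml,
    digest,
    lme4,
    lmerTest,
    rjags,
    coda
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
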