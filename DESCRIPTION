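Package: fearscr
Title: Skin-Conductance Analysis of Differential Fear Conditioning Across Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for differential fear-conditioning studies with
    skin-conductance outcomes across age groups. Builds the four-phase task
    schedules (habituation, acquisition, extinction, retention) with
    pseudorandom orderings and truncated-Gaussian inter-trial intervals;
    simulates synthetic cohorts (event-locked electrodermal recordings with a
    Bateman-kernel phasic response, ordinal fear ratings from a
    proportional-odds generative model, contingency reports, and head-motion
    traces); implements the electrodermal preprocessing chain (median filter,
    first-order Butterworth band-pass, downsampling to 100 Hz,
    baseline-corrected peak extraction, amplitude floor/ceiling rules,
    square-root transform); computes framewise displacement and motion
    censoring; and fits the study's statistical models (phase-wise linear
    mixed-effects models with Satterthwaite degrees of freedom, the
    extinction-retention early-trial differential, unconditioned-stimulus
    habituation, cumulative-link mixed models for ordinal ratings via adaptive
    Gauss-Hermite quadrature, contingency-awareness classification, and
    covariate sensitivity variants).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    lme4,
    lmerTest,
    MASS,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
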