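Package: painDCM
Title: Dynamic Causal Modeling of a Cortical-Limbic Pain Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and variational Bayesian inversion of
    three-region bilinear dynamic causal models (DCM) of the
    somatosensory-amygdala-hypothalamus pain network, with
    balloon-Windkessel hemodynamics, ROI-level GLM and first-eigenvariate
    summaries, fixed-effects Bayesian model selection with family-level
    inference over a 16-model/3-family space, and group-by-time ANOVA
    comparison of effective-connectivity parameters. Includes a synthetic
    cohort generator emulating a two-group, three-timepoint block-design
    fMRI study for end-to-end validation and parameter/model recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
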