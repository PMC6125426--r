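Package: cueddm
Title: Hierarchical Drift-Diffusion Modelling of Cued Expectation Bias
    with Catch-Trial FIR Timecourse Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how probabilistic cues bias perceptual
    decisions before and after sensory input. Implements the Wiener
    first-passage-time likelihood of the drift-diffusion model (with
    inter-trial variability in drift, starting point and non-decision
    time), hierarchical Bayesian estimation of three cue-bias model
    variants (starting-point bias, drift-rate bias, or both) via adaptive
    Metropolis-within-Gibbs, DIC-based model comparison, posterior
    hypothesis tests and posterior predictive checks. Also provides the
    surrounding behavioural pipeline (EWMA fast-guess filtering,
    Greenhouse-Geisser corrected repeated-measures ANOVA, Sidak pairwise
    tests), catch-trial FIR deconvolution of ROI-averaged BOLD time
    series with peak extraction, design-separability diagnostics,
    ROI growing on statistical maps, a prediction/surprise decomposition
    of event-related peaks, and a synthetic-data generator that
    reproduces the probabilistic face/house task design end to end.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
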