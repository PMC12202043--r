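Package: urbanvar
Title: Variance Partitioning of Repeated Behavioral Measures Along
    Urbanization Gradients
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how among-individual, within-individual and
    total phenotypic variance in repeatedly measured behavioral traits differ
    between habitats and along a continuous urbanization gradient.  Provides
    heterogeneous-variance Bayesian mixed models (Gaussian, ordinal-threshold
    and Poisson log-normal responses) fitted by Gibbs/Metropolis sampling with
    group-specific among-individual and residual variances; posterior variance
    decomposition into among-individual, year, fixed-effect and residual
    components; mean-standardized comparisons via log coefficient-of-variation
    ratios (lnCVR), log response ratios (lnRR) and log repeatability ratios
    (lnRPT); a two-step posterior-propagated regression of per-location
    variation on impervious-surface metrics with Bayesian R-squared scale
    selection; impervious-surface quantification in circular buffers around
    nest boxes; and a synthetic-data generator with exact ground truth for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
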