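Package: mnarsens
Title: Missing-Not-at-Random Sensitivity Analysis with Elicited Expert Priors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for sensitivity analysis of randomised trials whose
    patient-reported outcomes may be missing not at random (MNAR).
    Expert opinion about the mean outcome of questionnaire
    non-responders is represented as truncated split-normal
    distributions, pooled across experts by equal-weight linear opinion
    pooling into mixtures of bivariate split normals, and propagated
    through a Bayesian pattern-mixture model for a two-arm
    cluster-randomised trial.  Includes EQ-5D-5L utility scoring and
    PSS-SR severity bands for presenting outcome scales to experts,
    synthetic generators for trials with controllable MNAR missingness
    and for expert panels, scenario comparison against
    missing-at-random and complete-case references, and density-strip
    displays of treatment-effect posteriors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    withr
Config/testthat/edition: 3
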