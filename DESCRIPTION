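Package: stratpower
Title: Biomarker-Stratified Trial Power Simulation for Optic Neuropathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based power analysis for clinical trials in traumatic
    optic neuropathy that use retinal ganglion cell complex (GCC) thickness
    loss as a stratification biomarker. Provides a seeded synthetic-cohort
    generator, an ordinary-least-squares calibration linking GCC thickness
    loss to retinal ganglion cell somata loss with coefficient-uncertainty
    propagation, a Monte-Carlo engine estimating trial power with and without
    severity stratification (including minimal-sample-size search and power
    surfaces over sample size, effect size and biomarker quality), a
    subset-resampling estimator of longitudinal progression detection rates
    with age-adjusted GCC thinning, and pre/post outcome analysis of treated
    cohorts stratified by baseline biomarker severity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
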