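Package: glogrank
Title: Generalized Logrank-Type Tests for Treatment Regimes in SMARTs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Inverse-probability-weighted logrank-type tests of equality of
    the hazard functions associated with an arbitrary set of multistage
    treatment regimes, computed from sequential multiple assignment
    randomized trial (SMART) or observational time-to-event data.  Provides
    representations of SMART designs (stages, feasibility strata,
    randomization probabilities), enumeration of embedded regimes,
    propensity models (known, stratified maximum likelihood, logistic),
    influence-function sandwich covariance estimation with residual
    adjustment for estimated propensities and covariate augmentation, a
    generalized-inverse chi-squared quadratic form, and a SMART simulator
    for calibration of operating characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
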