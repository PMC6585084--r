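Package: biphasr
Title: Biphasic Growth and Pace-of-Life Analysis for Size-Selected Medaka
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate life-history traits (age at maturation,
    reproductive investment and the allometric exponent of maximal potential
    growth) from longitudinal length-at-age data using the Quince-Boukal
    biphasic growth model fitted by nonlinear mixed-effects models with
    moving-average residual correlation, and to analyse feeding and boldness
    assays with zero-inflated negative binomial mixed models. Includes a
    synthetic-data generator that emulates a two-line by two-food medaka
    rearing experiment so every stage of the pipeline can be exercised and
    validated by parameter-recovery simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    nlme,
    glmmTMB,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
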