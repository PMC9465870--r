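Package: sleepmr
Title: Linear and Nonlinear Mendelian Randomization for Sleep Duration and
    Pregnancy Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying effects of habitual sleep duration on pregnancy
    and perinatal outcomes with genetic instruments. Implements residual-
    stratification nonlinear Mendelian randomization (per-stratum Wald ratios
    with Cochran's Q and meta-regression tests of nonlinearity), split
    cross-over two-sample Mendelian randomization with inverse-variance
    weighted, MR-Egger, weighted-median and leave-one-out estimators,
    fixed-effects meta-analysis across cohorts, and the observational
    comparison of categorical versus midpoint-coded exposure models with a
    likelihood-ratio nonlinearity test and Rubin's-rules pooling across
    imputations. A synthetic-cohort generator with known ground truth
    (Hardy-Weinberg genotypes, an unweighted genetic risk score calibrated to a
    target variance explained, integer-reported exposure, rare binary outcomes,
    configurable exposure-outcome shapes, transmitted fetal genotypes and
    missingness mechanisms) drives calibration, recovery and bias-property
    checks for every stage.
License: MIT
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
    metafor,
    optparse
Config/testthat/edition: 3
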