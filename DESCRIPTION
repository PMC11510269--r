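Package: mrmediate
Title: Two-Sample Mendelian Randomization with Mediation Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for two-sample Mendelian randomization from GWAS summary
    statistics: instrument selection with strength screening (R-squared and
    F statistics), effect-allele harmonization, univariable causal estimation
    (Wald ratio, inverse-variance weighted, MR-Egger, weighted median), a
    sensitivity battery (Cochran's Q, MR-PRESSO global/outlier/distortion
    tests, leave-one-out), multivariable MR for direct effects, and a
    two-step/MVMR mediation engine computing product-of-coefficients
    indirect effects and proportions mediated with delta-method
    uncertainties. Includes a generator of exposure/mediator/outcome
    summary-statistic triads from a known linear structural model, and a
    config-driven pipeline that runs the full workflow and writes tabular
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
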