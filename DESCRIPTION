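Package: mediateMR
Title: Two-Sample Mendelian Randomization with Two-Step Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Instrument selection, harmonization, and causal-effect
    estimation for two-sample Mendelian randomization from GWAS summary
    statistics, including inverse-variance-weighted, MR-Egger, weighted
    median and weighted mode estimators, a sensitivity battery (Cochran Q,
    Egger intercept, MR-PRESSO, leave-one-out, FDR adjustment), two-step
    mediation analysis with delta-method confidence intervals and mediated
    proportions, and a synthetic summary-statistics generator with known
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'utils.R'
    'sumstats-io.R'
    'instruments.R'
    'estimators.R'
    'sensitivity.R'
    'mediation.R'
    'synthetic.R'
    'pipeline.R'
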