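Package: pfs2surr
Title: Trial-Level Surrogacy Evaluation of PFS2 for Overall Survival in Breast Cancer Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating progression-free survival 2 (PFS2) and PFS1
    as trial-level surrogate endpoints for overall survival (OS) in randomized
    controlled trials. Implements sample-size-weighted least-squares regression
    of log hazard ratios, weighted Pearson correlation with percentile-bootstrap
    confidence intervals, correlation strength bands and IQWiG surrogate-validity
    classification, endpoint maturity and information-fraction stratification,
    leave-one-out sensitivity analysis, Spearman-based secondary analyses of
    long-term OS drift and arm-level medians, and a synthetic trial-set
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
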