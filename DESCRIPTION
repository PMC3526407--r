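Package: dfctest
Title: Distributional Fold Change Test for Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the distributional fold change (DFC) test, a
    signal-to-noise statistic for two-class differential expression analysis
    whose null model -- the expression-dependent variance of the null log
    fold-change distribution and an expression-dependent total-variance
    threshold -- is estimated from the whole feature population of a log2
    expression matrix.  Provides expression-dependent significance (alpha)
    and power (beta) thresholds for fold change, feature ranking by the DFC
    score, Welch t and plain fold-change baseline rankers, ROC / AUC /
    standardized partial AUC / Youden index evaluation machinery with
    paired AUC comparisons, and a seeded generator of synthetic two-class
    expression data with expression-dependent variance trends and optional
    FFPE-like fold-change compression.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
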