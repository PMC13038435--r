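Package: lpmd
Title: Local Promoter Methylation Disorder Analysis for DNA Methylation Arrays and WGBS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies local DNA methylation disorder from beta-value
    matrices using sliding genomic windows, calls differentially methylated
    disorder regions (DMDRs) between sample groups by an effect-size-first
    strategy, builds consensus logistic biomarker panels with resampling-based
    evaluation, tests longitudinal disorder trends across treatment
    timepoints, and provides cross-platform concordance utilities for
    array/WGBS comparisons. Includes a seeded synthetic-methylome generator
    so every analysis step can be exercised without external data, plus a
    command-line interface for pipeline use.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    randomForest,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
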