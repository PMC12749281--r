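Package: diagentropy
Title: Entropy Removal and Accuracy Metrics for Diagnostic Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how much diagnostic uncertainty a clinical feature
    removes. Treats a dichotomous feature as a decision-tree split of a
    patient population into test-positive and test-negative nodes and
    measures the Shannon-entropy reduction ("entropy removal") that the
    split achieves, alongside conventional 2x2 accuracy metrics
    (sensitivity, specificity, PPV, NPV, Youden's J, diagnostic odds
    ratio). Includes an accuracy-versus-information quadrant
    classification, Pearson correlation reports relating entropy removal
    to each accuracy metric, CSV feature-table ingestion and export, a
    synthetic cohort generator with planted ground-truth controls, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
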