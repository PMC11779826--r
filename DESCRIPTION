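Package: ehrimpact
Title: Impact and Interaction Scores for Deep Tabular Clinical Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how a binary exposure modifies clinical risk
    with an explainable deep-learning workflow on tabular electronic health
    record (EHR) data. Provides a synthetic EHR cohort generator with a
    logistic outcome model, planted interactions and two-source noisy outcome
    labels; baseline characterization via absolute standardized differences;
    a residual feed-forward (ResNet-style) binary classifier trained with
    random under-sampling, binary cross-entropy and F1-based early stopping;
    finite-difference impact scores and pairwise interaction scores of any
    black-box probability model with percentile-bootstrap confidence
    intervals over the full training pipeline; a multivariate logistic
    regression benchmark; and one-command pipeline orchestration and
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
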