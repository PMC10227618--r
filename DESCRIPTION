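Package: screensim
Title: Active-Learning Simulation for Systematic-Review Screening Prioritisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates certainty-based active-learning pipelines for
    title/abstract screening in systematic reviews on labeled or synthetic
    corpora. Provides corpus input/output with deduplication, a synthetic
    generator for highly imbalanced clustered corpora, sparse tf-idf and dense
    paragraph-embedding feature extraction with classifier-feature
    compatibility rules, a classifier registry including a deep
    separable-convolution network trained with a loss-delta early-stopping
    rule, a screening engine with prior selection, training-set rebalancing,
    stop rules and mid-review model switching, and trajectory-based
    evaluation statistics: recall curves, work saved over sampling (WSS@k),
    time to discovery (TD/ATD), relevant records found (RRF@X%), and
    rank-order cohesion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    e1071,
    ranger,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
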