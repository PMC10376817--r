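Package: clearfpp
Title: Supervised Feature Scoring by Class-Wise Embedding and Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the ClearF family of supervised feature-scoring
    methods for biomarker prioritization on expression-like matrices.
    Each feature is scored by the difference between its reconstruction
    error under a low-dimensional embedding of all samples and the sum of
    its reconstruction errors under per-class embeddings, so that features
    well explained within classes but poorly explained globally -- i.e.
    class-discriminative features -- score highly. Includes the
    single-component variant (ClearF-one), the feature-wise clustered
    variant (ClearF++) with k-means or Deep Embedded Clustering, a
    stratified cross-validation harness with leakage-free feature
    selection, cross-fold rank aggregation, and a synthetic expression
    generator with planted class-informative features and correlated
    feature blocks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    kernlab,
    pROC,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
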