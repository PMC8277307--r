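Package: stancetopics
Title: Stance Classification and Topic Geometry for Social-Media Vaccine Discourse
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing pro- and antivaccine discourse in short
    social-media texts: collection hygiene (keyword pruning by median weekly
    count, tweet-id deduplication), tweet-aware tokenization and sparse
    count features, one-vs-all l1-regularized logistic stance classification
    with minority oversampling and stratified k-fold cross-validation,
    K-means topic extraction with silhouette-based model selection,
    intertopic-distinctiveness and intratopic-consistency cluster-geometry
    statistics with group comparison by t-test, Cohen kappa inter-rater
    reliability, and a synthetic tweet-corpus generator with planted topic
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    glmnet,
    jsonlite,
    ggplot2,
    tibble,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
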