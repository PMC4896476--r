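Package: skinqsar
Title: Integrated QSAR, Similarity and Structural-Alert Prediction of
    Skin Sensitization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the skin-sensitization potential of small molecules by
    combining three complementary lines of evidence: potency-stratified QSAR
    classifier variants, path-based fingerprint similarity to known sensitizers
    and non-sensitizers, and SMARTS structural alerts for skin-protein reactive
    groups. Component votes are merged by a weighted knowledge-based consensus
    (or a trained meta-classifier) into a sensitizer / non-sensitizer /
    indeterminate call. Includes the full supporting pipeline: t-test and
    correlation-based (CFS/best-first) feature selection, direct, separation
    and cross-validation train/test splits, Y-randomization, diverse-subset
    selection, performance metrics with indeterminate exclusion, and a
    synthetic benchmark generator with planted electrophilic sub-structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    randomForest,
    e1071,
    rpart,
    nnet,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
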