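Package: srnaugment
Title: Metadata Augmentation for Small RNA Expression Profiles
Version: 0.1.0
Authors@R: person("SEA", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts missing sample metadata (tissue group, sex, age class)
    from small RNA sequencing expression profiles using a fully connected
    neural network and a two-stage random forest, validates them with
    stratified fivefold cross-validation and one-dataset-out splits, and
    explains the network's decisions with DeepLIFT (Rescale rule)
    attribution, including class-average marker scores, top-N marker lists
    and feature-ablation class stability/similarity analyses. Ships a
    negative-binomial cohort simulator with planted markers, dataset-level
    batch effects and zero inflation so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
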