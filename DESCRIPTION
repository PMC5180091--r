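Package: puForest
Title: Positive-Unlabeled Random-Forest Ranking of Cancer Driver Genes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ranks genes as candidate cancer drivers (tumor suppressors or
    oncogenes) from a mixed-type gene feature table using a positive-unlabeled
    random-forest ensemble with stratified down-sampled bootstraps and exact
    out-of-bag posterior scoring. Includes the label-assembly rule engine that
    builds high/medium/low-confidence driver tiers from multi-source evidence,
    a feature-preparation pipeline (derived features, sparse- and
    correlated-feature removal, k-nearest-neighbor imputation), the tiered
    precision-at-N and TSG-versus-OG ROC evaluation protocol, enrichment
    statistics for the protein-size by chromatin-annotation analysis, and a
    synthetic-universe generator for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Rcpp,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    caret,
    pROC,
    randomForest,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
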