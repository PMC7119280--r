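Package: netfeat
Title: Network-Based Gene Expression Features for Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative evaluation machinery for network-based gene-expression
    features in binary outcome prediction. Builds mutual k-nearest-neighbor
    co-expression networks and ingests protein-protein interaction edge lists,
    derives fifteen gene- and network-based feature types (neighborhood mean,
    maximum, minimum, median, variance, neighbors-only average, and edge sums),
    screens features with Student's t-tests under Benjamini-Hochberg false
    discovery rate control, scores cross-cohort signature robustness via
    top-gene overlap fold changes, and evaluates feature types with repeated
    stratified cross-validated logistic regression (AUC), including a combined
    network features ensemble and a sample-size subsampling experiment. Ships a
    multi-cohort synthetic data generator with planted modular network
    structure, distributed class signal, and cohort batch effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    igraph,
    Matrix,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
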