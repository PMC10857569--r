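Package: ccdrank
Title: Ranking Cancer Associations for circRNAs and Drugs on a
    Tri-Partite Heterogeneous Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assembles a tri-partite heterogeneous association network of
    circRNAs, drugs and cancers, computes Gaussian interaction profile
    (GIP) kernel node features, learns explicit edge embeddings with a
    message-passing graph neural network whose aggregation, combination,
    activation, layer-connectivity, layer-aggregation and readout-pooling
    operations are selected by stochastic differentiable architecture
    search (Gumbel-softmax relaxation), and ranks candidate cancers per
    circRNA or drug query with a LambdaMART learning-to-rank model.
    Includes query-grouped and within-query cross-validation protocols
    with leakage-safe edge masking, ranking metrics (AUC, AUPR, NDCG,
    NDCG at k, MRR, MAP, truncated ROC), RankLib-dialect dataset input
    and output, and a synthetic tri-partite network generator with
    planted low-rank structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
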