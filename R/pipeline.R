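# End-to-end orchestration: fold construction, leakage-safe feature and
# GNN training, edge embedding, LambdaMART ranking and evaluation.

#' Degree-popularity baseline scores for candidate pairs
#'
#' Scores every (query, cancer) pair by the cancer's degree in the
#' training network's query-cancer relation. A non-learning popularity
#' ranker: any useful model should beat it.
#'
#' @param train_net Training `hetnet`.
#' @param pairs `candidate_pairs` to score.
#' @param query_type `"circRNA"` or `"drug"`.
#' @return Numeric score vector aligned with `pairs` rows.
#' @export
degree_baseline_scores <- function(train_net, pairs,
                                   query_type = c("circRNA", "drug")) {
  query_type <- match.arg(query_type)
  rel <- relation_for_query(query_type)
  e <- train_net$edges[train_net$edges$relation == rel, , drop = FALSE]
  deg <- table(e$target_id)
  out <- as.numeric(deg[pairs$cancer_id])
  out[is.na(out)] <- 0
  out
}

#' Build a ranking dataset from candidate pairs and edge embeddings
#'
#' @param pairs `candidate_pairs`.
#' @param embeddings Edge-embedding matrix, one row per pair (from
#'   [embed_edges()]).
#' @return A `ranking_dataset` whose features are the edge embeddings.
#' @export
make_ranking_dataset <- function(pairs, embeddings) {
  stopifnot(nrow(embeddings) == nrow(pairs))
  ranking_dataset(pairs$label, pairs$query_id, pairs$cancer_id, embeddings)
}

#' Run the full prediction pipeline under cross-validation
#'
#' For each evaluated fold: masks the fold's test query-cancer edges from
#' the network, recomputes GIP node features from the training network
#' only, searches and trains the edge-embedding GNN on training pairs,
#' embeds all pairs, trains LambdaMART on the training ranking dataset and
#' scores the held-out fold. Metrics are averaged over the evaluated
#' folds; a degree-popularity baseline is evaluated on the same folds.
#'
#' @param net A `hetnet`.
#' @param query_type `"circRNA"` or `"drug"`.
#' @param scenario `"novel_query"` (query-grouped folds) or
#'   `"known_query"` (within-query folds).
#' @param n_folds Number of folds (default 5).
#' @param eval_folds Which folds to evaluate (default: fold 1; use
#'   `seq_len(n_folds)` for the full protocol).
#' @param gnn A `gnn_config`.
#' @param lmart A `lambdamart_config`.
#' @param seed Root seed; fold, search and ranker seeds derive from it.
#' @param k Ranking cutoff for NDCG@k / ROCk (default 10).
#' @param feature_scope Profile scope for the GIP node features
#'   ([node_attribute_features()]); the default `"all"` concatenates each
#'   node's profiles across every relation it participates in, so all
#'   three association sources inform the attribute features.
#' @param n_models Independently seeded GNN models per fold; their edge
#'   embeddings are concatenated as ranking features and their link
#'   scores averaged (a small ensemble for variance reduction).
#' @return List of class `pipeline_result`: `report`, `baseline_report`,
#'   `folds`, per-fold `details` (architecture, predictions).
#' @export
run_pipeline <- function(net, query_type = c("circRNA", "drug"),
                         scenario = c("known_query", "novel_query"),
                         n_folds = 5, eval_folds = 1,
                         gnn = gnn_config(), lmart = lambdamart_config(),
                         seed = 1, k = 10, feature_scope = "all",
                         n_models = 2) {
  query_type <- match.arg(query_type)
  scenario <- match.arg(scenario)
  stopifnot(all(eval_folds %in% seq_len(n_folds)))
  pairs <- enumerate_candidate_pairs(net, query_type)
  folds <- if (scenario == "novel_query")
    grouped_query_folds(pairs, n_folds, seed = seed)
  else within_query_folds(pairs, n_folds, seed = seed)

  fold_dfs <- list()
  base_dfs <- list()
  details <- list()
  for (f in eval_folds) {
    a <- folds$assignment
    train_ix <- a$sample[a$fold != f]
    test_ix <- a$sample[a$fold == f]
    train_pairs <- pairs[train_ix, , drop = FALSE]
    test_pairs <- pairs[test_ix, , drop = FALSE]
    attr(train_pairs, "query_type") <- query_type

    train_net <- mask_test_edges(net, folds, f, query_type)
    feats <- node_attribute_features(train_net, task = query_type,
                                     scope = feature_scope)

    emb_train <- emb_test <- NULL
    score_test <- 0
    archs <- list()
    for (m in seq_len(n_models)) {
      gcfg <- gnn
      gcfg$seed <- seed * 1000L + f * 10L + m
      sr <- gnn_search(train_net, feats, train_pairs, cfg = gcfg,
                       query_type = query_type)
      etr <- embed_edges(sr$fit, train_pairs)
      ete <- embed_edges(sr$fit, test_pairs)
      emb_train <- cbind(emb_train, etr$embeddings)
      emb_test <- cbind(emb_test, ete$embeddings)
      score_test <- score_test + ete$scores / n_models
      archs[[m]] <- sr$arch
    }

    ds_train <- make_ranking_dataset(train_pairs, emb_train)
    lcfg <- lmart
    lcfg$seed <- seed * 1000L + f
    model <- train_lambdamart(ds_train, lcfg)
    ds_test <- make_ranking_dataset(test_pairs, emb_test)
    pred <- predict_scores(model, ds_test)

    fold_dfs[[as.character(f)]] <- data.frame(
      qid = test_pairs$query_id, did = test_pairs$cancer_id,
      label = test_pairs$label, score = pred$scores,
      stringsAsFactors = FALSE)
    base_dfs[[as.character(f)]] <- data.frame(
      qid = test_pairs$query_id, did = test_pairs$cancer_id,
      label = test_pairs$label,
      score = degree_baseline_scores(train_net, test_pairs, query_type),
      stringsAsFactors = FALSE)
    details[[as.character(f)]] <- list(arch = archs[[1]],
                                       archs = archs,
                                       gnn_scores = score_test)
  }
  structure(list(report = evaluate_run(fold_dfs, k = k),
                 baseline_report = evaluate_run(base_dfs, k = k),
                 folds = folds, details = details,
                 scenario = scenario, query_type = query_type),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline (", x$scenario, ", query type ", x$query_type, ")\n",
      sep = "")
  print(x$report)
  cat("Degree baseline:\n")
  print(x$baseline_report)
  invisible(x)
}
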