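# Cross-validation protocols for the two application scenarios:
# novel-query ranking (query-grouped folds, no qid shared between train and
# test) and known-query ranking (within-query random folds).

local_seed <- function(seed) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    later <- function() assign(".Random.seed", old, envir = globalenv())
  } else {
    later <- function() rm(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  later
}

new_fold_assignment <- function(pairs, fold, n_folds, scenario, seed) {
  stopifnot(nrow(pairs) == length(fold))
  out <- data.frame(sample = seq_len(nrow(pairs)),
                    qid = pairs$query_id,
                    did = pairs$cancer_id,
                    label = pairs$label,
                    fold = fold,
                    stringsAsFactors = FALSE)
  structure(list(assignment = out, n_folds = n_folds,
                 scenario = scenario, seed = seed),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat("Fold assignment (", x$scenario, "): ", nrow(x$assignment),
      " samples, ", x$n_folds, " folds, seed ", x$seed, "\n", sep = "")
  print(table(x$assignment$fold))
  invisible(x)
}

#' Query-grouped folds for novel-query evaluation (Scenario 1)
#'
#' Randomly partitions the distinct query ids into `n_folds` groups; every
#' candidate pair of a query is assigned to its query's fold, so train and
#' test query-id sets are disjoint in every fold.
#'
#' @param pairs A `candidate_pairs` data.frame (see
#'   [enumerate_candidate_pairs()]).
#' @param n_folds Number of folds (default 5).
#' @param seed Integer RNG seed (mandatory).
#' @return A `fold_assignment` object.
#' @export
grouped_query_folds <- function(pairs, n_folds = 5, seed) {
  stopifnot(is.data.frame(pairs), n_folds >= 2)
  qids <- unique(pairs$query_id)
  if (length(qids) < n_folds)
    stop("fewer distinct query ids (", length(qids), ") than folds (",
         n_folds, ")")
  restore <- local_seed(seed); on.exit(restore())
  shuffled <- sample(qids)
  qfold <- setNames(rep_len(seq_len(n_folds), length(qids)), shuffled)
  new_fold_assignment(pairs, unname(qfold[pairs$query_id]),
                      n_folds, "novel_query", seed)
}

#' Within-query random folds for known-query evaluation (Scenario 2)
#'
#' Randomly partitions all samples into `n_folds` subsets. By default the
#' split is stratified per query id so every query with at least `n_folds`
#' samples contributes to both train and test in every fold; queries with
#' fewer samples land in fewer folds (noted via a message).
#'
#' @inheritParams grouped_query_folds
#' @param stratify Stratify by query id (default `TRUE`); `FALSE` restores
#'   a plain random partition of samples.
#' @return A `fold_assignment` object.
#' @export
within_query_folds <- function(pairs, n_folds = 5, seed, stratify = TRUE) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 1, n_folds >= 2)
  restore <- local_seed(seed); on.exit(restore())
  fold <- integer(nrow(pairs))
  if (stratify) {
    small <- 0L
    for (ix in split(seq_len(nrow(pairs)), pairs$query_id)) {
      if (length(ix) < n_folds) small <- small + 1L
      fold[sample(ix)] <- rep_len(sample(n_folds), length(ix))
    }
    if (small > 0)
      message(small, " query/queries with fewer samples than folds ",
              "appear in fewer than ", n_folds, " folds")
  } else {
    fold[sample(seq_len(nrow(pairs)))] <- rep_len(seq_len(n_folds),
                                                  nrow(pairs))
  }
  new_fold_assignment(pairs, fold, n_folds, "known_query", seed)
}

#' Remove a fold's test edges from the network (leakage control)
#'
#' Returns the training network for a fold: observed query-cancer edges
#' whose pair lies in the test fold are removed before feature computation
#' and GNN training. Edges of other relations (e.g. circRNA-drug) are kept,
#' so novel queries remain connected through cross-type links. Nodes are
#' kept even if masking leaves them edge-free in the evaluated relation.
#'
#' @param net A `hetnet` object.
#' @param folds A `fold_assignment`.
#' @param fold_idx Fold to hold out (1-based).
#' @param query_type `"circRNA"` or `"drug"`: which query-cancer relation
#'   the folds evaluate.
#' @return A `hetnet` containing the training edges only (node set and
#'   ordering unchanged).
#' @export
mask_test_edges <- function(net, folds, fold_idx,
                            query_type = c("circRNA", "drug")) {
  stopifnot(inherits(net, "hetnet"), inherits(folds, "fold_assignment"))
  query_type <- match.arg(query_type)
  if (!(fold_idx %in% seq_len(folds$n_folds)))
    stop("fold_idx out of range")
  rel <- relation_for_query(query_type)
  a <- folds$assignment
  test_pos <- a[a$fold == fold_idx & a$label == 1, , drop = FALSE]
  drop_key <- paste(rel, test_pos$qid, test_pos$did, sep = "\r")
  e <- net$edges
  keep <- !(paste(e$relation, e$source_id, e$target_id, sep = "\r")
            %in% drop_key)
  train <- net
  train$edges <- e[keep, , drop = FALSE]
  rownames(train$edges) <- NULL
  train
}

#' Export a fold assignment as TSV
#'
#' @param folds A `fold_assignment`.
#' @param path Output path.
#' @export
write_folds <- function(folds, path) {
  stopifnot(inherits(folds, "fold_assignment"))
  write.table(folds$assignment, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
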