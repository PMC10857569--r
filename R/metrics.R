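# Ranking and classification metrics. All ranking metrics operate on label
# vectors already sorted in ranked order (descending score); use
# rank_labels() to produce that order with the documented id tie-break.

#' Order labels by descending score with identifier tie-break
#'
#' @param scores Numeric scores.
#' @param labels Binary relevance labels.
#' @param ids Optional candidate identifiers used to break score ties
#'   (lexicographic); defaults to input position.
#' @return `labels` reordered by rank.
#' @export
rank_labels <- function(scores, labels, ids = NULL) {
  stopifnot(length(scores) == length(labels))
  if (is.null(ids)) ids <- seq_along(scores)
  labels[order(-scores, ids)]
}

dcg_at_k <- function(labels_ranked, k) {
  k <- min(k, length(labels_ranked))
  if (k < 1) return(0)
  l <- labels_ranked[seq_len(k)]
  sum((2^l - 1) / log2(seq_len(k) + 1))
}

#' Normalized discounted cumulative gain at k
#'
#' Binary gain `2^label - 1`, discount `log2(rank + 1)`, normalised by the
#' ideal DCG at the same cutoff. A list with no relevant item scores 0.
#'
#' @param labels_ranked Binary labels in ranked order.
#' @param k Cutoff (default: full list length).
#' @return NDCG@k in [0, 1].
#' @export
ndcg_at_k <- function(labels_ranked, k = length(labels_ranked)) {
  stopifnot(k >= 1)
  ideal <- dcg_at_k(sort(labels_ranked, decreasing = TRUE), k)
  if (ideal == 0) return(0)
  dcg_at_k(labels_ranked, k) / ideal
}

#' Mean reciprocal rank over queries
#'
#' @param rankings List of ranked binary label vectors, one per query.
#' @return Mean over queries of 1 / rank-of-first-relevant (0 when a query
#'   has no relevant item).
#' @export
mrr <- function(rankings) {
  stopifnot(length(rankings) >= 1)
  mean(vapply(rankings, function(l) {
    r <- which(l == 1)
    if (!length(r)) 0 else 1 / r[1]
  }, numeric(1)))
}

average_precision <- function(labels_ranked) {
  pos <- which(labels_ranked == 1)
  if (!length(pos)) return(0)
  mean(seq_along(pos) / pos)
}

#' Mean average precision over queries
#'
#' @param rankings List of ranked binary label vectors, one per query.
#' @return MAP in [0, 1]; queries without relevant items contribute 0.
#' @export
mean_ap <- function(rankings) {
  stopifnot(length(rankings) >= 1)
  mean(vapply(rankings, average_precision, numeric(1)))
}

#' Area under the ROC curve
#'
#' Mann-Whitney rank statistic with midrank tie correction.
#'
#' @param labels Binary labels (both classes must be present).
#' @param scores Numeric scores.
#' @return AUC in [0, 1].
#' @export
auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: only one class present")
  r <- rank(scores)  # midranks under ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-function integration: candidates enter by descending score
#' threshold (score ties enter together) and the area is
#' `sum over thresholds of (recall_i - recall_{i-1}) * precision_i`.
#'
#' @inheritParams auc
#' @return AUPR in (0, 1].
#' @export
aupr <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == length(labels))
    stop("AUPR undefined: only one class present")
  o <- order(-scores)
  s <- scores[o]
  l <- labels[o]
  tp <- cumsum(l)
  n <- seq_along(l)
  # group boundaries: last index of each tied-score block
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  prec <- tp[last] / n[last]
  rec <- tp[last] / n1
  sum(diff(c(0, rec)) * prec)
}

#' Truncated per-query ROC area (ROCk)
#'
#' Each query's ranked list is truncated at rank `k`. Over the truncated
#' prefix, TPR is normalised by the query's total positives and FPR by its
#' total negatives (the curve ends where truncation ends). The area is then
#' normalised by the maximum area reachable at that truncation, the
#' rectangle `TPR_end * FPR_end`. A prefix with no negatives (and at least
#' one positive) scores 1; a prefix with no positives scores 0. With
#' `k >= length` this equals the per-query AUC. Queries lacking either
#' class in the full list are dropped from the macro average.
#'
#' @param rankings List of ranked binary label vectors, one per query.
#' @param k Truncation rank.
#' @return Macro-averaged ROCk in [0, 1], or `NA` if no query has both
#'   classes.
#' @export
roc_k <- function(rankings, k) {
  stopifnot(k >= 1)
  vals <- vapply(rankings, function(l) {
    p <- sum(l == 1)
    n <- sum(l == 0)
    if (p == 0 || n == 0) return(NA_real_)
    pre <- l[seq_len(min(k, length(l)))]
    tpr_end <- sum(pre == 1) / p
    fpr_end <- sum(pre == 0) / n
    if (fpr_end == 0) return(if (tpr_end > 0) 1 else 0)
    if (tpr_end == 0) return(0)
    # step curve: each negative step adds TPR-so-far * (1/n)
    area <- sum(cumsum(pre == 1)[pre == 0] / p) / n
    area / (tpr_end * fpr_end)
  }, numeric(1))
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

split_rankings <- function(df) {
  stopifnot(all(c("qid", "label", "score") %in% names(df)))
  ids <- if ("did" %in% names(df)) df$did else
    stats::ave(seq_len(nrow(df)), df$qid, FUN = seq_along)
  lapply(split(seq_len(nrow(df)), df$qid), function(ix)
    rank_labels(df$score[ix], df$label[ix], ids[ix]))
}

#' Evaluate ranked predictions over cross-validation folds
#'
#' Computes, per fold: pooled AUC/AUPR over all pairs, macro (per-query
#' mean) NDCG, NDCG@k, MRR, MAP, and ROCk; also a per-cancer AUC view
#' (pairs grouped by candidate cancer). Fold metrics are then averaged to
#' the final report.
#'
#' @param fold_results List of data.frames, one per fold, with columns
#'   `qid`, `did`, `label`, `score`.
#' @param k Cutoff for NDCG@k and ROCk (default 10).
#' @return List of class `metric_report`: `mean` (fold-averaged metrics),
#'   `per_fold`, `per_cancer` (median and per-cancer AUCs pooled over
#'   folds).
#' @export
evaluate_run <- function(fold_results, k = 10) {
  stopifnot(is.list(fold_results), length(fold_results) >= 1)
  per_fold <- lapply(fold_results, function(df) {
    stopifnot(all(c("qid", "did", "label", "score") %in% names(df)))
    r <- split_rankings(df)
    both <- sum(df$label == 1) > 0 && sum(df$label == 0) > 0
    c(auc = if (both) auc(df$label, df$score) else NA_real_,
      aupr = if (both) aupr(df$label, df$score) else NA_real_,
      ndcg = mean(vapply(r, ndcg_at_k, numeric(1))),
      ndcg_at_k = mean(vapply(r, ndcg_at_k, numeric(1), k = k)),
      mrr = mrr(r),
      map = mean_ap(r),
      roc_k = roc_k(r, k))
  })
  tab <- do.call(rbind, per_fold)
  pooled <- do.call(rbind, fold_results)
  per_cancer <- vapply(split(seq_len(nrow(pooled)), pooled$did), function(ix) {
    l <- pooled$label[ix]
    if (sum(l == 1) == 0 || sum(l == 0) == 0) return(NA_real_)
    auc(l, pooled$score[ix])
  }, numeric(1))
  out <- list(mean = colMeans(tab, na.rm = TRUE),
              per_fold = tab,
              per_cancer = list(
                auc = per_cancer,
                median = if (all(is.na(per_cancer))) NA_real_
                         else median(per_cancer, na.rm = TRUE)))
  class(out) <- "metric_report"
  out
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Fold-averaged metrics (", nrow(x$per_fold), " fold(s)):\n", sep = "")
  print(round(x$mean, 4))
  cat("Per-cancer median AUC:", round(x$per_cancer$median, 4), "\n")
  invisible(x)
}

#' Serialize a metric report to JSON (and optionally TSV)
#'
#' @param report A `metric_report`.
#' @param path Output path for the JSON report.
#' @param tsv Optional path for a per-fold metric table as TSV.
#' @export
write_metric_report <- function(report, path, tsv = NULL) {
  jsonlite::write_json(
    list(mean = as.list(report$mean),
         per_fold = apply(report$per_fold, 1, as.list),
         per_cancer_median = report$per_cancer$median,
         per_cancer_auc = as.list(report$per_cancer$auc)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(tsv)) {
    tab <- data.frame(fold = seq_len(nrow(report$per_fold)),
                      report$per_fold, check.names = FALSE)
    write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
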