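# Shared fixture builders. Everything is generated in code; no data files.

# Write three relation edge-list TSVs into a temp dir; returns named paths.
write_edge_fixture <- function(edges_by_rel, dir = withr::local_tempdir()) {
  paths <- character(0)
  for (rel in names(edges_by_rel)) {
    p <- file.path(dir, paste0(rel, ".tsv"))
    write.table(edges_by_rel[[rel]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths[rel] <- p
  }
  paths
}

# A small deterministic tri-partite network: 4 circRNAs, 2 drugs,
# 3 cancers.
tiny_net <- function() {
  edges <- rbind(
    data.frame(source_id = c("r1", "r1", "r2", "r3"), source_type = "circRNA",
               target_id = c("c1", "c2", "c1", "c3"), target_type = "cancer",
               relation = "circ_cancer", stringsAsFactors = FALSE),
    data.frame(source_id = c("d1", "d2"), source_type = "drug",
               target_id = c("c2", "c3"), target_type = "cancer",
               relation = "drug_cancer", stringsAsFactors = FALSE),
    data.frame(source_id = c("r1", "r4"), source_type = "circRNA",
               target_id = c("d1", "d2"), target_type = "drug",
               relation = "circ_drug", stringsAsFactors = FALSE))
  build_network(edges)
}

# Random symmetric adjacency over n nodes (no self loops).
random_adjacency <- function(n, p = 0.3) {
  a <- matrix(0, n, n)
  up <- which(upper.tri(a))
  a[up] <- rbinom(length(up), 1, p)
  a + t(a)
}

# Brute-force explicit-loop message-passing oracle, independent of the
# package's vectorised/sparse implementation.
mpnn_oracle <- function(H, adj, aggregate, combine, activation, W_self,
                        W_neigh, W_comb = NULL, prelu = 0.25) {
  n <- nrow(H)
  d <- ncol(W_self)
  out <- matrix(0, n, d)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] > 0)
    msgs <- lapply(nb, function(u) as.numeric(H[u, , drop = FALSE] %*% W_neigh))
    x <- if (!length(msgs)) rep(0, d) else switch(aggregate,
      sum = Reduce(`+`, msgs),
      mean = Reduce(`+`, msgs) / length(msgs),
      max = do.call(pmax, msgs))
    s <- as.numeric(H[v, , drop = FALSE] %*% W_self)
    comb <- switch(combine,
      sum = s + x,
      concat = as.numeric(c(s, x) %*% W_comb))
    out[v, ] <- switch(activation,
      relu = pmax(comb, 0),
      prelu = ifelse(comb < 0, prelu * comb, comb))
  }
  out
}

# Brute-force AUC: count positive/negative pairs, ties worth 1/2.
auc_bruteforce <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# Brute-force truncated-ROC oracle: walk the ranked prefix accumulating
# (FPR, TPR) points, integrate by trapezoid, normalise by the rectangle
# spanned by the endpoint.
roc_k_oracle <- function(labels_ranked, k) {
  P <- sum(labels_ranked == 1)
  N <- sum(labels_ranked == 0)
  pre <- labels_ranked[seq_len(min(k, length(labels_ranked)))]
  fpr <- c(0, cumsum(pre == 0) / N)
  tpr <- c(0, cumsum(pre == 1) / P)
  m <- length(fpr)
  if (fpr[m] == 0) return(if (tpr[m] > 0) 1 else 0)
  if (tpr[m] == 0) return(0)
  area <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  area / (fpr[m] * tpr[m])
}

# Exact two-sided Wilcoxon rank-sum p-value by enumerating every
# assignment of the pooled ranks to group 1.
wilcox_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(pooled), n1)
  w_all <- apply(combs, 2, function(ix) sum(r[ix]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}
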