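# LambdaMART listwise learning-to-rank over edge-embedding features, with
# RankLib-dialect dataset I/O. The boosted trees are fit to LambdaRank
# gradients: pairwise logistic lambdas weighted by the |Delta NDCG| of
# swapping the pair, with Newton leaf values.

#' LambdaMART configuration
#'
#' Defaults follow the published parameter analysis: 1000 trees, learning
#' rate 0.1, 256 threshold candidates, minimum leaf support 1; the number
#' of leaves keeps the RankLib default of 10.
#'
#' @param n_trees Number of boosting iterations.
#' @param learning_rate Shrinkage applied to each tree's leaf values.
#' @param n_threshold_candidates Maximum equal-frequency quantile split
#'   thresholds per feature, computed once before boosting.
#' @param min_leaf_support Minimum training documents per leaf.
#' @param n_leaves Maximum leaves per tree.
#' @param seed Integer RNG seed.
#' @return List of class `lambdamart_config`.
#' @export
lambdamart_config <- function(n_trees = 1000, learning_rate = 0.1,
                              n_threshold_candidates = 256,
                              min_leaf_support = 1, n_leaves = 10,
                              seed = 1) {
  stopifnot(n_trees >= 1, learning_rate > 0, n_threshold_candidates >= 1,
            min_leaf_support >= 1, n_leaves >= 2)
  structure(list(n_trees = as.integer(n_trees),
                 learning_rate = learning_rate,
                 n_threshold_candidates = as.integer(n_threshold_candidates),
                 min_leaf_support = as.integer(min_leaf_support),
                 n_leaves = as.integer(n_leaves), seed = as.integer(seed)),
            class = "lambdamart_config")
}

# ---- RankLib-dialect I/O ---------------------------------------------------

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a ranking dataset in the RankLib (SVMlight-style) dialect
#'
#' One line per sample: `<label> qid:<qid> 1:<v1> 2:<v2> ... # did=<did>`.
#' Feature values are rendered with full precision so that
#' `read_ranklib(write_ranklib(x))` reproduces `x` exactly.
#'
#' @param ds A `ranking_dataset`.
#' @param path Output path.
#' @export
write_ranklib <- function(ds, path) {
  stopifnot(inherits(ds, "ranking_dataset"))
  featstr <- apply(ds$features, 1, function(v)
    paste(sprintf("%d:%s", seq_along(v), fmt_num(v)), collapse = " "))
  lines <- sprintf("%d qid:%s %s # did=%s", ds$label, ds$qid, featstr,
                   ds$did)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ranklib
#' @export
read_ranklib <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty RankLib file: ", path)
  n <- length(lines)
  label <- integer(n); qid <- character(n); did <- character(n)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    line <- lines[i]
    hash <- regmatches(line, regexpr("# did=\\S+", line))
    if (length(hash)) {
      did[i] <- sub("# did=", "", hash)
      line <- trimws(sub("#.*$", "", line))
    } else did[i] <- NA_character_
    tok <- strsplit(line, " +")[[1]]
    if (length(tok) < 2 || !grepl("^[01]$", tok[1]) ||
        !grepl("^qid:", tok[2]))
      stop("unparseable RankLib line ", i, " in ", path)
    label[i] <- as.integer(tok[1])
    qid[i] <- sub("^qid:", "", tok[2])
    fv <- tok[-(1:2)]
    m <- regmatches(fv, regexec("^([0-9]+):(.+)$", fv))
    if (any(lengths(m) != 3))
      stop("unparseable feature token on line ", i, " in ", path)
    ix <- as.integer(vapply(m, `[`, character(1), 2))
    vals <- suppressWarnings(as.numeric(vapply(m, `[`, character(1), 3)))
    if (anyNA(vals)) stop("non-numeric feature value on line ", i)
    if (!identical(ix, seq_along(ix)))
      stop("non-contiguous feature indices on line ", i, " in ", path)
    feats[[i]] <- vals
  }
  width <- unique(lengths(feats))
  if (length(width) != 1)
    stop("inconsistent feature width across lines in ", path)
  ranking_dataset(label, qid, did, do.call(rbind, feats))
}

# ---- training --------------------------------------------------------------

# Equal-frequency quantile thresholds, then integer bins (0-based).
bin_features <- function(x, n_thresholds) {
  boundaries <- lapply(seq_len(ncol(x)), function(j) {
    q <- unique(quantile(x[, j], probs = seq_len(n_thresholds - 1) /
                                   n_thresholds, type = 7, names = FALSE))
    q
  })
  bins <- vapply(seq_len(ncol(x)), function(j)
    findInterval(x[, j], boundaries[[j]]), integer(nrow(x)))
  if (!is.matrix(bins)) bins <- matrix(bins, nrow = nrow(x))
  list(bins = bins, boundaries = boundaries,
       nbins = vapply(boundaries, length, integer(1)) + 1L)
}

max_dcg <- function(n_pos) {
  if (n_pos == 0) return(0)
  sum(1 / log2(seq_len(n_pos) + 1))
}

#' Train a LambdaMART ranking model
#'
#' Gradient-boosted regression trees fit to LambdaRank gradients: for each
#' within-query pair (relevant i, non-relevant j), the pairwise logistic
#' lambda (`sigma = 1`) is weighted by the |Delta NDCG| of swapping the
#' pair at the current ranks; per-leaf Newton steps use the corresponding
#' second derivatives. Split thresholds are equal-frequency quantiles per
#' feature computed once before boosting.
#'
#' @param ds A `ranking_dataset` grouped by `qid`.
#' @param cfg A `lambdamart_config`.
#' @return A `lambdamart` model (tree ensemble + binning thresholds).
#' @export
train_lambdamart <- function(ds, cfg = lambdamart_config()) {
  stopifnot(inherits(ds, "ranking_dataset"),
            inherits(cfg, "lambdamart_config"))
  n <- length(ds$label)
  groups <- split(seq_len(n), ds$qid)
  has_pair <- vapply(groups, function(ix)
    any(ds$label[ix] == 1) && any(ds$label[ix] == 0), logical(1))
  if (!any(has_pair))
    stop("no query has both a relevant and a non-relevant document; ",
         "nothing to learn")
  groups <- groups[has_pair]

  # global pair lists (i relevant, j not) and per-pair ideal DCG
  pairs_i <- integer(0); pairs_j <- integer(0); pair_maxdcg <- numeric(0)
  for (ix in groups) {
    pos <- ix[ds$label[ix] == 1]
    neg <- ix[ds$label[ix] == 0]
    grid <- expand.grid(i = pos, j = neg, KEEP.OUT.ATTRS = FALSE)
    pairs_i <- c(pairs_i, grid$i)
    pairs_j <- c(pairs_j, grid$j)
    pair_maxdcg <- c(pair_maxdcg, rep(max_dcg(length(pos)), nrow(grid)))
  }

  bf <- bin_features(ds$features, cfg$n_threshold_candidates)
  eps <- 1e-10
  s <- numeric(n)
  ranks <- numeric(n)
  trees <- vector("list", cfg$n_trees)
  for (t in seq_len(cfg$n_trees)) {
    for (ix in groups) {
      o <- order(-s[ix], ds$did[ix])
      ranks[ix[o]] <- seq_along(ix)
    }
    disc <- 1 / log2(1 + ranks)
    delta <- abs(disc[pairs_i] - disc[pairs_j]) / pair_maxdcg
    rho <- 1 / (1 + exp(s[pairs_i] - s[pairs_j]))
    lam <- rho * delta
    hes <- rho * (1 - rho) * delta
    g <- scatter_sum(c(lam, -lam), c(pairs_i, pairs_j), n)
    h <- scatter_sum(c(hes, hes), c(pairs_i, pairs_j), n)
    tr <- lmart_build_tree(bf$bins, g, h, bf$nbins, cfg$n_leaves,
                           cfg$min_leaf_support, eps)
    step <- cfg$learning_rate * tr$pred
    s <- s + step
    tr$value <- cfg$learning_rate * tr$value
    tr$pred <- NULL
    trees[[t]] <- tr
  }
  structure(list(trees = trees, boundaries = bf$boundaries,
                 n_features = ncol(ds$features), cfg = cfg,
                 train_scores = s),
            class = "lambdamart")
}

scatter_sum <- function(x, group, n) {
  r <- rowsum(x, group)
  out <- numeric(n)
  out[as.integer(rownames(r))] <- r[, 1]
  out
}

#' @export
print.lambdamart <- function(x, ...) {
  cat("LambdaMART ensemble:", length(x$trees), "trees,",
      x$n_features, "features\n")
  invisible(x)
}

tree_predict <- function(tree, bins) {
  n <- nrow(bins)
  out <- numeric(n)
  route <- function(node, ix) {
    if (!length(ix)) return(invisible(NULL))
    f <- tree$feature[node]
    if (f < 0) {
      out[ix] <<- tree$value[node]
      return(invisible(NULL))
    }
    go_left <- bins[ix, f + 1L] <= tree$bin[node]
    route(tree$left[node] + 1L, ix[go_left])
    route(tree$right[node] + 1L, ix[!go_left])
  }
  route(1L, seq_len(n))
  out
}

#' Score a ranking dataset and produce per-query ranked lists
#'
#' @param model A `lambdamart` model.
#' @param ds A `ranking_dataset` with the training feature width.
#' @return List with `scores` (per-sample) and `ranking`, a data.frame
#'   `(qid, did, score, label)` sorted per query by descending score with
#'   ties broken by `did` (lexicographic).
#' @export
predict_scores <- function(model, ds) {
  stopifnot(inherits(model, "lambdamart"), inherits(ds, "ranking_dataset"))
  if (ncol(ds$features) != model$n_features)
    stop("feature width ", ncol(ds$features),
         " does not match training width ", model$n_features)
  n <- nrow(ds$features)
  bins <- vapply(seq_len(model$n_features), function(j)
    findInterval(ds$features[, j], model$boundaries[[j]]), integer(n))
  if (!is.matrix(bins)) bins <- matrix(bins, nrow = n)
  scores <- numeric(n)
  for (tr in model$trees) scores <- scores + tree_predict(tr, bins)
  df <- data.frame(qid = ds$qid, did = ds$did, score = scores,
                   label = ds$label, stringsAsFactors = FALSE)
  df <- df[order(df$qid, -df$score, df$did), , drop = FALSE]
  rownames(df) <- NULL
  list(scores = scores, ranking = df)
}

#' Serialize / restore a LambdaMART model as JSON
#'
#' @param model A `lambdamart` model.
#' @param path File path.
#' @export
write_lmart_model <- function(model, path) {
  jsonlite::write_json(
    list(format_version = 1L,
         n_features = model$n_features,
         cfg = unclass(model$cfg),
         boundaries = model$boundaries,
         trees = model$trees),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lmart_model
#' @export
read_lmart_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  trees <- lapply(obj$trees, function(tr)
    list(feature = as.integer(unlist(tr$feature)),
         bin = as.integer(unlist(tr$bin)),
         left = as.integer(unlist(tr$left)),
         right = as.integer(unlist(tr$right)),
         value = as.numeric(unlist(tr$value))))
  structure(list(trees = trees,
                 boundaries = lapply(obj$boundaries,
                                     function(b) as.numeric(unlist(b))),
                 n_features = as.integer(obj$n_features),
                 cfg = do.call(lambdamart_config, lapply(obj$cfg, unlist))),
            class = "lambdamart")
}
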