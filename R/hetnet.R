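#' @useDynLib ccdrank, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median p.adjust rnorm runif plogis quantile rbinom sd cor setNames uniroot wilcox.test aggregate
#' @importFrom utils read.table write.table head
NULL

# Relation classes of the tri-partite network and the node types each one
# connects (source type first). Edges are undirected; the relation label is
# kept as metadata.
HET_RELATIONS <- list(
  circ_cancer = c("circRNA", "cancer"),
  drug_cancer = c("drug", "cancer"),
  circ_drug   = c("circRNA", "drug")
)

HET_NODE_TYPES <- c("circRNA", "drug", "cancer")

node_key <- function(type, id) paste(type, id, sep = "\r")

#' Read typed edge lists from TSV files
#'
#' Reads one TSV file per relation class. Each file must have a header line
#' `source_id<TAB>target_id`; lines starting with `#` are ignored. The node
#' types of each endpoint are implied by which file the row comes from
#' (`circ_cancer`: circRNA to cancer, `drug_cancer`: drug to cancer,
#' `circ_drug`: circRNA to drug). Duplicate rows within a relation are
#' collapsed with a warning.
#'
#' @param paths Named character vector or list; names must be a subset of
#'   `c("circ_cancer", "drug_cancer", "circ_drug")`, values are file paths.
#' @return A `data.frame` of typed edges with columns `source_id`,
#'   `source_type`, `target_id`, `target_type`, `relation`.
#' @export
read_edge_lists <- function(paths) {
  paths <- as.list(paths)
  if (is.null(names(paths)) || !all(names(paths) %in% names(HET_RELATIONS)))
    stop("`paths` must be named with relations among: ",
         paste(names(HET_RELATIONS), collapse = ", "))
  out <- lapply(names(paths), function(rel) {
    path <- paths[[rel]]
    if (!file.exists(path)) stop("edge-list file not found: ", path)
    tab <- tryCatch(
      read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                 colClasses = "character", quote = "", fill = FALSE,
                 stringsAsFactors = FALSE),
      error = function(e) stop("malformed edge list '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    )
    if (!all(c("source_id", "target_id") %in% names(tab)))
      stop("edge list '", path,
           "' must have header columns source_id and target_id")
    if (nrow(tab) == 0) return(empty_edges())
    bad <- which(!nzchar(tab$source_id) | !nzchar(tab$target_id))
    if (length(bad))
      stop("edge list '", path, "': empty identifier on data row ", bad[1])
    loop <- which(tab$source_id == tab$target_id)
    if (length(loop))
      stop("edge list '", path, "': source and target identifier coincide ('",
           tab$source_id[loop[1]], "') on data row ", loop[1],
           "; self loops / cross-type identifier reuse within an edge ",
           "are not allowed")
    types <- HET_RELATIONS[[rel]]
    edges <- data.frame(source_id = tab$source_id, source_type = types[1],
                        target_id = tab$target_id, target_type = types[2],
                        relation = rel, stringsAsFactors = FALSE)
    dup <- duplicated(paste(edges$source_id, edges$target_id, sep = "\r"))
    if (any(dup)) {
      warning(sum(dup), " duplicate row(s) collapsed in '", path, "'",
              call. = FALSE)
      edges <- edges[!dup, , drop = FALSE]
    }
    edges
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

empty_edges <- function() {
  data.frame(source_id = character(), source_type = character(),
             target_id = character(), target_type = character(),
             relation = character(), stringsAsFactors = FALSE)
}

validate_edges <- function(edges) {
  req <- c("source_id", "source_type", "target_id", "target_type", "relation")
  if (!is.data.frame(edges) || !all(req %in% names(edges)))
    stop("`edges` must be a data.frame with columns ",
         paste(req, collapse = ", "))
  bad_rel <- setdiff(unique(edges$relation), names(HET_RELATIONS))
  if (length(bad_rel)) stop("unknown relation(s): ",
                            paste(bad_rel, collapse = ", "))
  for (rel in unique(edges$relation)) {
    types <- HET_RELATIONS[[rel]]
    sel <- edges$relation == rel
    ok <- edges$source_type[sel] == types[1] & edges$target_type[sel] == types[2]
    if (!all(ok))
      stop("edge endpoint types do not match relation '", rel, "'")
  }
  if (any(edges$source_id == edges$target_id &
          edges$source_type == edges$target_type))
    stop("self loops are not allowed")
  key <- paste(edges$relation, edges$source_id, edges$target_id, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate edges within a relation")
  invisible(edges)
}

#' Assemble a heterogeneous network from typed edges
#'
#' Builds the tri-partite circRNA/drug/cancer network. Only nodes incident to
#' at least one edge are part of the network (isolated-node pruning): the node
#' set is exactly the union of edge endpoints.
#'
#' @param edges Typed edge `data.frame` as returned by [read_edge_lists()].
#' @return An object of class `hetnet` with components `nodes` (data.frame
#'   `id`, `type`), `edges`, and precomputed endpoint indices.
#' @export
build_network <- function(edges) {
  if (!is.data.frame(edges) || nrow(edges) == 0)
    stop("`edges` must be a non-empty data.frame of typed edges")
  validate_edges(edges)
  nodes <- unique(data.frame(
    id = c(edges$source_id, edges$target_id),
    type = c(edges$source_type, edges$target_type),
    stringsAsFactors = FALSE))
  nodes$type <- factor(nodes$type, levels = HET_NODE_TYPES)
  nodes <- nodes[order(nodes$type, nodes$id), , drop = FALSE]
  nodes$type <- as.character(nodes$type)
  rownames(nodes) <- NULL
  idx <- setNames(seq_len(nrow(nodes)), node_key(nodes$type, nodes$id))
  edges$source_idx <- unname(idx[node_key(edges$source_type, edges$source_id)])
  edges$target_idx <- unname(idx[node_key(edges$target_type, edges$target_id)])
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, index = idx),
            class = "hetnet")
}

#' @export
print.hetnet <- function(x, ...) {
  nt <- table(factor(x$nodes$type, levels = HET_NODE_TYPES))
  er <- table(factor(x$edges$relation, levels = names(HET_RELATIONS)))
  cat("Heterogeneous network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  cat("  nodes:", paste(sprintf("%s=%d", names(nt), nt), collapse = ", "), "\n")
  cat("  edges:", paste(sprintf("%s=%d", names(er), er), collapse = ", "), "\n")
  invisible(x)
}

het_nodes_of_type <- function(net, type) {
  net$nodes$id[net$nodes$type == type]
}

#' Summary statistics of a heterogeneous network
#'
#' @param net A `hetnet` object.
#' @return A list of class `hetnet_stats`: total node/edge counts, per-type
#'   node counts, per-relation edge counts, and a per-type degree summary.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "hetnet"))
  deg <- tabulate(c(net$edges$source_idx, net$edges$target_idx),
                  nbins = nrow(net$nodes))
  deg_summary <- lapply(HET_NODE_TYPES, function(ty) {
    d <- deg[net$nodes$type == ty]
    if (!length(d)) return(NULL)
    list(min = min(d), median = median(d), max = max(d),
         mean = mean(d))
  })
  names(deg_summary) <- HET_NODE_TYPES
  out <- list(
    n_nodes = nrow(net$nodes),
    n_edges = nrow(net$edges),
    nodes_by_type = as.list(table(factor(net$nodes$type,
                                         levels = HET_NODE_TYPES))),
    edges_by_relation = as.list(table(factor(net$edges$relation,
                                             levels = names(HET_RELATIONS)))),
    degree = deg_summary[!vapply(deg_summary, is.null, logical(1))]
  )
  class(out) <- "hetnet_stats"
  out
}

#' @export
print.hetnet_stats <- function(x, ...) {
  cat("Nodes:", x$n_nodes, "(",
      paste(sprintf("%s=%d", names(x$nodes_by_type),
                    unlist(x$nodes_by_type)), collapse = ", "), ")\n")
  cat("Edges:", x$n_edges, "(",
      paste(sprintf("%s=%d", names(x$edges_by_relation),
                    unlist(x$edges_by_relation)), collapse = ", "), ")\n")
  invisible(x)
}

relation_for_query <- function(query_type) {
  switch(query_type,
         circRNA = "circ_cancer",
         drug = "drug_cancer",
         stop("unknown query_type: ", query_type,
              " (must be 'circRNA' or 'drug')"))
}

#' Enumerate all query-cancer candidate pairs
#'
#' Produces the Cartesian product of query-type nodes (circRNAs or drugs)
#' and cancer nodes. A pair is labelled 1 iff it is an observed edge of the
#' corresponding relation; all unobserved pairs are labelled 0 (negatives).
#'
#' @param net A `hetnet` object.
#' @param query_type `"circRNA"` or `"drug"`.
#' @return A `data.frame` of class `candidate_pairs` with columns
#'   `query_id`, `cancer_id`, `label` and attribute `query_type`.
#' @export
enumerate_candidate_pairs <- function(net, query_type = c("circRNA", "drug")) {
  stopifnot(inherits(net, "hetnet"))
  query_type <- match.arg(query_type)
  rel <- relation_for_query(query_type)
  queries <- het_nodes_of_type(net, query_type)
  cancers <- het_nodes_of_type(net, "cancer")
  if (!length(queries) || !length(cancers))
    stop("network lacks nodes of type ", query_type, " or cancer")
  pairs <- expand.grid(cancer_id = cancers, query_id = queries,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[, c("query_id", "cancer_id")]
  obs <- net$edges[net$edges$relation == rel, , drop = FALSE]
  pos_key <- paste(obs$source_id, obs$target_id, sep = "\r")
  pairs$label <- as.integer(
    paste(pairs$query_id, pairs$cancer_id, sep = "\r") %in% pos_key)
  rownames(pairs) <- NULL
  attr(pairs, "query_type") <- query_type
  class(pairs) <- c("candidate_pairs", "data.frame")
  pairs
}

#' Derive circRNA-drug sensitivity edges by Wilcoxon test and FDR control
#'
#' For every (circRNA, drug) pair, samples are split into high/low groups at
#' the median of the circRNA's expression (strictly above the median is
#' "high"), drug response is compared between the groups with a two-sided
#' Wilcoxon rank-sum test, p-values are Benjamini-Hochberg adjusted across
#' all tested pairs, and an edge is emitted iff FDR < `alpha`.
#'
#' @param expr Numeric matrix, circRNA expression; rows = circRNAs (rownames
#'   required), columns = samples (colnames required).
#' @param resp Numeric matrix, drug response; rows = drugs, columns = samples.
#' @param alpha FDR level in (0, 1); default 0.05.
#' @return Typed edge `data.frame` (relation `circ_drug`), with attribute
#'   `"tests"` holding the full per-pair test table (`circ`, `drug`, `p`, `q`).
#' @export
derive_sensitivity_edges <- function(expr, resp, alpha = 0.05) {
  stopifnot(is.matrix(expr), is.matrix(resp),
            !is.null(rownames(expr)), !is.null(rownames(resp)),
            !is.null(colnames(expr)), !is.null(colnames(resp)),
            is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  samples <- intersect(colnames(expr), colnames(resp))
  if (length(samples) < 4)
    stop("fewer than 4 shared samples between expression and response")
  expr <- expr[, samples, drop = FALSE]
  resp <- resp[, samples, drop = FALSE]
  rows <- list()
  for (ci in rownames(expr)) {
    med <- median(expr[ci, ])
    hi <- expr[ci, ] > med
    if (sum(hi) < 2 || sum(!hi) < 2) {
      warning("circRNA '", ci, "': fewer than 2 samples in a group; ",
              "all its pairs skipped", call. = FALSE)
      next
    }
    for (dj in rownames(resp)) {
      p <- suppressWarnings(
        wilcox.test(resp[dj, hi], resp[dj, !hi],
                    alternative = "two.sided")$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        circ = ci, drug = dj, p = p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- empty_edges()
    attr(out, "tests") <- data.frame(circ = character(), drug = character(),
                                     p = numeric(), q = numeric())
    return(out)
  }
  tests <- do.call(rbind, rows)
  tests$q <- p.adjust(tests$p, method = "BH")
  keep <- tests$q < alpha
  out <- if (any(keep)) {
    data.frame(source_id = tests$circ[keep], source_type = "circRNA",
               target_id = tests$drug[keep], target_type = "drug",
               relation = "circ_drug", stringsAsFactors = FALSE)
  } else empty_edges()
  attr(out, "tests") <- tests
  out
}

#' Write / read the canonical merged edge list
#'
#' Round-trips the 5-column TSV
#' (`source_id, source_type, target_id, target_type, relation`).
#'
#' @param edges Typed edge data.frame.
#' @param path Output file path.
#' @export
write_edge_list <- function(edges, path) {
  validate_edges(edges)
  cols <- c("source_id", "source_type", "target_id", "target_type", "relation")
  write.table(edges[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  edges <- read.table(path, header = TRUE, sep = "\t", quote = "",
                      colClasses = "character", stringsAsFactors = FALSE)
  validate_edges(edges)
  edges
}

# Sparse symmetric adjacency over the network's node ordering, optionally
# restricted to a subset of relations.
het_adjacency <- function(net, relations = NULL) {
  stopifnot(inherits(net, "hetnet"))
  e <- net$edges
  if (!is.null(relations)) e <- e[e$relation %in% relations, , drop = FALSE]
  n <- nrow(net$nodes)
  if (!nrow(e))
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n)))
  Matrix::sparseMatrix(i = c(e$source_idx, e$target_idx),
                       j = c(e$target_idx, e$source_idx),
                       x = 1, dims = c(n, n), use.last.ij = TRUE)
}
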