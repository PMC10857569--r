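#' Binary interaction profile matrix between two node types
#'
#' Rows are the nodes of `row_type`, columns the nodes of `col_type` (both in
#' network order); entry (i, j) is 1 iff the corresponding edge is observed.
#' The relation is determined by the (unordered) type pair.
#'
#' @param net A `hetnet` object.
#' @param row_type,col_type Node types among `"circRNA"`, `"drug"`,
#'   `"cancer"`.
#' @return Binary matrix with row/column names set to node identifiers.
#' @export
interaction_profile <- function(net, row_type, col_type) {
  stopifnot(inherits(net, "hetnet"))
  rel <- NULL
  for (r in names(HET_RELATIONS)) {
    ty <- HET_RELATIONS[[r]]
    if (setequal(ty, c(row_type, col_type)) && row_type != col_type) rel <- r
  }
  if (is.null(rel))
    stop("no relation connects node types '", row_type, "' and '",
         col_type, "'")
  rows <- het_nodes_of_type(net, row_type)
  cols <- het_nodes_of_type(net, col_type)
  if (!length(rows) || !length(cols))
    stop("network has no nodes of type ", row_type, " or ", col_type)
  m <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  e <- net$edges[net$edges$relation == rel, , drop = FALSE]
  if (nrow(e)) {
    # relation stores endpoints as (source = first type of the relation)
    if (HET_RELATIONS[[rel]][1] == row_type) {
      m[cbind(e$source_id, e$target_id)] <- 1
    } else {
      m[cbind(e$target_id, e$source_id)] <- 1
    }
  }
  m
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Computes `K(i, j) = exp(-gamma * ||IP(i) - IP(j)||^2)` over the profile
#' vectors, with the bandwidth normalised by the mean squared profile norm:
#' `gamma = 1 / mean_i ||IP(i)||^2` (and `gamma = 1` when all profiles are
#' zero).
#'
#' @param profiles Interaction profile matrix (see [interaction_profile()]).
#' @param axis `"rows"` to compare row profiles, `"cols"` for columns.
#' @return Symmetric similarity matrix with unit diagonal, entries in [0, 1].
#' @export
gip_kernel <- function(profiles, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  p <- if (axis == "cols") t(profiles) else profiles
  if (!is.matrix(p) || nrow(p) == 0) stop("empty profile matrix")
  sq <- rowSums(p^2)
  gamma <- if (all(sq == 0)) 1 else 1 / mean(sq)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(p)
  d2[d2 < 0] <- 0  # numerical guard
  k <- exp(-gamma * d2)
  k <- (k + t(k)) / 2
  diag(k) <- 1
  dimnames(k) <- list(rownames(p), rownames(p))
  k
}

#' Fuse a GIP similarity matrix with an external similarity source
#'
#' Entries where `other` is defined (non-`NA`) are replaced by the
#' element-wise mean of the two matrices; entries where `other` is `NA`, or
#' the whole matrix when `other` is `NULL`, keep the GIP value. `other` is
#' the plug-in point for precomputed semantic / functional / chemical
#' similarity; no ontology or structure computation is built in.
#'
#' @param gip Square similarity matrix from [gip_kernel()].
#' @param other Optional square matrix with identical row/column names and
#'   ordering; `NA` marks undefined entries.
#' @return Fused similarity matrix (symmetric, unit diagonal).
#' @export
fuse_similarity <- function(gip, other = NULL) {
  if (is.null(other)) return(gip)
  if (!identical(dim(gip), dim(other)) ||
      !identical(dimnames(gip), dimnames(other)))
    stop("`other` must match the GIP matrix's dimensions and node ordering")
  fused <- gip
  def <- !is.na(other)
  fused[def] <- (gip[def] + other[def]) / 2
  fused <- (fused + t(fused)) / 2
  diag(fused) <- 1
  fused
}

#' Per-type node attribute feature tables
#'
#' Each node's feature vector is its row of the fused similarity matrix of
#' its own type; the vector length is the number of nodes of that type. The
#' profiles feeding the GIP kernel depend on the prediction task: for
#' circRNA-cancer ranking, circRNA and cancer profiles come from the
#' circRNA-cancer incidence matrix and drug profiles from drug-cancer; for
#' drug-cancer ranking, drug and cancer profiles come from drug-cancer and
#' circRNA profiles from circRNA-cancer. With `scope = "all"` each type's
#' profile concatenates its incidence rows across every relation it
#' participates in.
#'
#' @param net A `hetnet` object.
#' @param task `"circRNA"` or `"drug"`: which query-cancer task the features
#'   serve.
#' @param scope `"task"` (default, per-task primary relation) or `"all"`
#'   (concatenated profiles).
#' @param external Optional named list of precomputed similarity matrices
#'   (names among `circRNA`, `drug`, `cancer`) fused in via
#'   [fuse_similarity()].
#' @return Named list of feature matrices, one per node type present.
#' @export
node_attribute_features <- function(net, task = c("circRNA", "drug"),
                                    scope = c("task", "all"),
                                    external = NULL) {
  stopifnot(inherits(net, "hetnet"))
  task <- match.arg(task)
  scope <- match.arg(scope)
  types <- intersect(HET_NODE_TYPES, unique(net$nodes$type))
  profile_of <- function(ty) {
    if (scope == "all") {
      mats <- list()
      for (r in names(HET_RELATIONS)) {
        rt <- HET_RELATIONS[[r]]
        if (ty %in% rt && all(rt %in% types)) {
          other <- setdiff(rt, ty)
          mats[[r]] <- interaction_profile(net, ty, other)
        }
      }
      if (!length(mats)) stop("node type '", ty, "' joins no relation")
      do.call(cbind, mats)
    } else {
      other <- switch(ty,
        circRNA = "cancer",
        drug = "cancer",
        cancer = if (task == "circRNA") "circRNA" else "drug")
      interaction_profile(net, ty, other)
    }
  }
  out <- lapply(types, function(ty) {
    k <- gip_kernel(profile_of(ty), axis = "rows")
    fuse_similarity(k, external[[ty]])
  })
  names(out) <- types
  out
}

#' Write / read a similarity matrix as TSV with identifier header
#'
#' @param sim Square similarity matrix with row/column names.
#' @param path File path.
#' @export
write_similarity <- function(sim, path) {
  stopifnot(is.matrix(sim), !is.null(rownames(sim)))
  write.table(data.frame(id = rownames(sim), sim, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$id
  storage.mode(m) <- "double"
  m
}
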