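# Synthetic tri-partite heterogeneous networks with planted low-rank
# cluster structure, plus a synthetic learning-to-rank dataset generator.
# Both are first-class, seeded simulators used throughout the test suite.

#' Configuration for the synthetic network generator
#'
#' Nodes of each type carry latent factors drawn around a small number of
#' cluster centres; the probability of an association is a logistic
#' function of the scaled inner product of the endpoint factors, with a
#' per-relation intercept calibrated so the expected edge density matches
#' `density`. With probability `noise` a pair's observed label is drawn at
#' the relation's base rate instead of its true probability (annotation
#' incompleteness / spurious edges), which keeps relations sparser than
#' the noise level feasible.
#'
#' @param n_circ,n_drug,n_cancer Node counts (desk-scale defaults 60/12/15).
#' @param latent_rank Latent factor dimension (default 4).
#' @param n_clusters Number of latent clusters per type (default 3).
#' @param density Named per-relation edge densities in (0, 1).
#' @param noise Probability that a pair's label is drawn at the base rate.
#' @param scale Logistic scale on the factor inner product.
#' @param cluster_sd Within-cluster factor spread relative to the
#'   unit-scale cluster centres; smaller values plant crisper clusters.
#' @param seed Integer RNG seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_circ = 60, n_drug = 12, n_cancer = 15,
                             latent_rank = 4, n_clusters = 3,
                             density = c(circ_cancer = 0.15,
                                         drug_cancer = 0.45,
                                         circ_drug = 0.30),
                             noise = 0.05, scale = 6, cluster_sd = 0.2,
                             seed = 1) {
  stopifnot(n_circ >= 1, n_drug >= 1, n_cancer >= 1, latent_rank >= 1,
            n_clusters >= 1, noise >= 0, noise < 0.5, scale > 0,
            cluster_sd >= 0)
  stopifnot(all(names(HET_RELATIONS) %in% names(density)),
            all(density > 0 & density < 1))
  structure(list(n_circ = n_circ, n_drug = n_drug, n_cancer = n_cancer,
                 latent_rank = latent_rank, n_clusters = n_clusters,
                 density = density, noise = noise, scale = scale,
                 cluster_sd = cluster_sd, seed = seed),
            class = "synthetic_config")
}

#' Table-1-scale preset configuration
#'
#' The real multi-source network's printed scale: 407 circRNAs, 24 drugs,
#' 46 cancers and exactly 614 / 523 / 1197 edges for the circRNA-cancer,
#' drug-cancer and circRNA-drug relations. Generated with exact per-relation
#' edge counts (see `exact_counts` of [generate_hetnet()]).
#'
#' @param seed Integer RNG seed.
#' @return A `synthetic_config` with attribute `exact_counts`.
#' @export
table1_config <- function(seed = 1) {
  counts <- c(circ_cancer = 614, drug_cancer = 523, circ_drug = 1197)
  sizes <- c(circ_cancer = 407 * 46, drug_cancer = 24 * 46,
             circ_drug = 407 * 24)
  cfg <- synthetic_config(n_circ = 407, n_drug = 24, n_cancer = 46,
                          density = counts / sizes, seed = seed)
  attr(cfg, "exact_counts") <- counts
  cfg
}

relation_dims <- function(cfg) {
  list(circ_cancer = c("circRNA", "cancer"),
       drug_cancer = c("drug", "cancer"),
       circ_drug = c("circRNA", "drug"))
}

#' Generate a synthetic heterogeneous network with planted structure
#'
#' @param cfg A `synthetic_config`.
#' @param exact_counts Optional named integer vector of per-relation edge
#'   counts; when given, exactly that many edges are drawn per relation by
#'   probability-weighted sampling without replacement (the noise level
#'   enters as a uniform mixture on the weights). Defaults to the
#'   `exact_counts` attribute of `cfg`, if any; otherwise edges are
#'   independent Bernoulli draws with noise flips.
#' @return List with components `net` (a `hetnet`), `truth` (latent
#'   factors and per-relation true probability matrices), and `edges`.
#' @export
generate_hetnet <- function(cfg, exact_counts = attr(cfg, "exact_counts")) {
  stopifnot(inherits(cfg, "synthetic_config"))
  restore <- local_seed(cfg$seed); on.exit(restore())
  sizes <- c(circRNA = cfg$n_circ, drug = cfg$n_drug, cancer = cfg$n_cancer)
  ids <- list(circRNA = sprintf("r%03d", seq_len(cfg$n_circ)),
              drug = sprintf("d%03d", seq_len(cfg$n_drug)),
              cancer = sprintf("c%03d", seq_len(cfg$n_cancer)))
  stopifnot(cfg$n_clusters <= cfg$latent_rank)
  # cluster centres live in a latent space shared by all three node types
  # (a cluster is a common biological context, e.g. a pathway), drawn as
  # orthonormal directions so same-cluster pairs align and cross-cluster
  # pairs are near-orthogonal regardless of the seed
  centers <- t(qr.Q(qr(matrix(rnorm(cfg$latent_rank^2), cfg$latent_rank)))[
    , seq_len(cfg$n_clusters), drop = FALSE])
  factors <- lapply(names(sizes), function(ty) {
    n <- sizes[[ty]]
    cl <- sample(rep_len(seq_len(cfg$n_clusters), n))
    f <- centers[cl, , drop = FALSE] +
      cfg$cluster_sd * matrix(rnorm(n * cfg$latent_rank), n, cfg$latent_rank)
    rownames(f) <- ids[[ty]]
    f
  })
  names(factors) <- names(sizes)

  probs <- list()
  edge_tabs <- list()
  for (rel in names(HET_RELATIONS)) {
    ty <- HET_RELATIONS[[rel]]
    ip <- cfg$scale * tcrossprod(factors[[ty[1]]], factors[[ty[2]]])
    noise <- cfg$noise
    target <- cfg$density[[rel]]
    # intercept so that E[density] = target; the noise mixture below keeps
    # the expectation at the target
    b <- uniroot(function(b) mean(plogis(ip + b)) - target,
                 lower = -80, upper = 80, extendInt = "yes")$root
    p <- plogis(ip + b)
    probs[[rel]] <- p
    # annotation noise: with probability `noise` the pair's label is drawn
    # at the relation's base rate instead of its true probability
    p_obs <- (1 - noise) * p + noise * target
    m <- matrix(0L, nrow(p), ncol(p), dimnames = dimnames(p))
    if (!is.null(exact_counts)) {
      k <- exact_counts[[rel]]
      if (k >= length(p_obs)) stop("infeasible exact edge count for ", rel)
      sel <- sample.int(length(p_obs), k, prob = as.vector(p_obs))
      m[sel] <- 1L
    } else {
      m[] <- rbinom(length(p_obs), 1, as.vector(p_obs))
      if (sum(m) == 0) stop("infeasible density: no edges drawn for ", rel)
    }
    edge_tabs[[rel]] <- m
  }

  edge_tabs <- rewire_isolated(edge_tabs, sizes, ids)

  edges <- do.call(rbind, lapply(names(edge_tabs), function(rel) {
    ty <- HET_RELATIONS[[rel]]
    w <- which(edge_tabs[[rel]] == 1L, arr.ind = TRUE)
    data.frame(source_id = rownames(edge_tabs[[rel]])[w[, 1]],
               source_type = ty[1],
               target_id = colnames(edge_tabs[[rel]])[w[, 2]],
               target_type = ty[2],
               relation = rel, stringsAsFactors = FALSE)
  }))
  rownames(edges) <- NULL
  net <- build_network(edges)
  list(net = net, edges = edges,
       truth = list(factors = factors, probs = probs, config = cfg))
}

# Guarantee degree >= 1 for every node while keeping per-relation edge
# counts fixed: an isolated node steals one endpoint slot from an edge
# whose same-role endpoint has total degree >= 2.
rewire_isolated <- function(edge_tabs, sizes, ids) {
  total_degree <- function() {
    deg <- lapply(names(sizes), function(ty) setNames(numeric(sizes[[ty]]),
                                                      ids[[ty]]))
    names(deg) <- names(sizes)
    for (rel in names(edge_tabs)) {
      ty <- HET_RELATIONS[[rel]]
      deg[[ty[1]]] <- deg[[ty[1]]] + rowSums(edge_tabs[[rel]])
      deg[[ty[2]]] <- deg[[ty[2]]] + colSums(edge_tabs[[rel]])
    }
    deg
  }
  for (ty in names(sizes)) {
    repeat {
      deg <- total_degree()
      iso <- names(deg[[ty]])[deg[[ty]] == 0]
      if (!length(iso)) break
      v <- iso[1]
      moved <- FALSE
      for (rel in names(edge_tabs)) {
        rt <- HET_RELATIONS[[rel]]
        if (!(ty %in% rt)) next
        m <- edge_tabs[[rel]]
        on_rows <- rt[1] == ty
        margin <- if (on_rows) rowSums(m) else colSums(m)
        other_deg <- deg[[ty]][names(margin)]
        # donors: same-role nodes with spare total degree and an edge whose
        # partner slot is still free for v
        donors <- names(margin)[margin >= 1 & other_deg >= 2]
        for (d in donors) {
          partners <- if (on_rows) colnames(m)[m[d, ] == 1] else
            rownames(m)[m[, d] == 1]
          free <- if (on_rows) partners[m[v, partners] == 0] else
            partners[m[partners, v] == 0]
          if (length(free)) {
            p <- free[1]
            if (on_rows) { m[d, p] <- 0L; m[v, p] <- 1L }
            else { m[p, d] <- 0L; m[p, v] <- 1L }
            edge_tabs[[rel]] <- m
            moved <- TRUE
            break
          }
        }
        if (moved) break
      }
      if (!moved)
        stop("could not rewire isolated node '", v,
             "': edge counts too small for the node set")
    }
  }
  edge_tabs
}

#' Generate a synthetic learning-to-rank dataset
#'
#' Per query, `n_docs` candidate documents with standard normal features;
#' relevant documents (`n_relevant` per query) have the first feature
#' shifted upward by `separation`, so at large separation a single
#' threshold on that feature ranks perfectly, and at `separation = 0` the
#' labels are independent of the features.
#'
#' @param n_queries,n_docs Dataset shape.
#' @param separation Mean shift for relevant documents (>= 0).
#' @param n_features Feature dimension (default 5).
#' @param n_relevant Relevant documents per query (default 4).
#' @param seed Integer RNG seed.
#' @return A `ranking_dataset`: list with `label`, `qid`, `did` vectors and
#'   a `features` matrix.
#' @export
generate_ranking_dataset <- function(n_queries, n_docs, separation,
                                     n_features = 5, n_relevant = 4,
                                     seed = 1) {
  stopifnot(n_queries >= 1, n_docs >= 2, separation >= 0,
            n_relevant >= 1, n_relevant < n_docs)
  restore <- local_seed(seed); on.exit(restore())
  n <- n_queries * n_docs
  qid <- rep(sprintf("q%03d", seq_len(n_queries)), each = n_docs)
  did <- rep(sprintf("c%03d", seq_len(n_docs)), times = n_queries)
  label <- as.vector(vapply(seq_len(n_queries), function(q) {
    l <- integer(n_docs); l[sample.int(n_docs, n_relevant)] <- 1L; l
  }, integer(n_docs)))
  x <- matrix(rnorm(n * n_features), n, n_features)
  x[, 1] <- x[, 1] + separation * label
  ranking_dataset(label, qid, did, x)
}

#' Construct a ranking dataset
#'
#' @param label Integer 0/1 relevance labels.
#' @param qid Query identifiers (one circRNA or drug per query).
#' @param did Candidate (cancer) identifiers.
#' @param features Numeric feature matrix, one row per sample.
#' @return A list of class `ranking_dataset`.
#' @export
ranking_dataset <- function(label, qid, did, features) {
  features <- as.matrix(features)
  stopifnot(length(label) == length(qid), length(qid) == length(did),
            nrow(features) == length(label), all(label %in% c(0, 1)))
  structure(list(label = as.integer(label), qid = as.character(qid),
                 did = as.character(did), features = features),
            class = "ranking_dataset")
}

#' @export
print.ranking_dataset <- function(x, ...) {
  cat("Ranking dataset:", length(x$label), "samples,",
      length(unique(x$qid)), "queries,", ncol(x$features), "features,",
      sum(x$label), "relevant\n")
  invisible(x)
}
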