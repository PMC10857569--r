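# Architecture-searched message-passing GNN producing explicit edge
# embeddings. Intra-layer operations (neighbour aggregation, self/neighbour
# combination, activation), inter-layer operations (layer connectivity,
# layer aggregation) and the readout pooling are selected by stochastic
# differentiable architecture search: each discrete choice is relaxed to a
# Gumbel-softmax mixture whose log-weights are trained jointly with the
# model weights, then discretised by per-decision argmax and retrained.

#' Default architecture search space
#'
#' Candidate sets per decision: per-layer neighbour aggregation
#' (`sum`/`max`/`mean`), self-neighbour combination (`sum`/`concat`),
#' activation (`relu`/`prelu`), layer connectivity
#' (`stack`/`skip_sum`/`skip_concat`); network-level layer aggregation
#' (`last`/`concat`/`max`/`none`) and edge readout pooling
#' (`sum`/`max`/`concat`).
#'
#' @return Named list of candidate vectors, class `search_space`.
#' @export
search_space <- function() {
  structure(list(
    aggregate = c("sum", "max", "mean"),
    combine = c("sum", "concat"),
    activation = c("relu", "prelu"),
    connect = c("stack", "skip_sum", "skip_concat"),
    layer_aggregation = c("last", "concat", "max", "none"),
    pool = c("sum", "max", "concat")
  ), class = "search_space")
}

#' Construct / validate a concrete GNN architecture
#'
#' @param layers List (length = number of layers) of per-layer choices,
#'   each a list with `aggregate`, `combine`, `activation`, `connect`.
#' @param layer_aggregation One of `last`, `concat`, `max`, `none`
#'   (`none` is an alias of `last`).
#' @param pool Readout pooling: `sum`, `max` or `concat`.
#' @return A list of class `gnn_architecture`.
#' @export
gnn_architecture <- function(layers, layer_aggregation = "last",
                             pool = "sum") {
  sp <- search_space()
  stopifnot(is.list(layers), length(layers) >= 1)
  for (l in layers) {
    stopifnot(l$aggregate %in% sp$aggregate, l$combine %in% sp$combine,
              l$activation %in% sp$activation, l$connect %in% sp$connect)
  }
  stopifnot(layer_aggregation %in% sp$layer_aggregation, pool %in% sp$pool)
  structure(list(layers = layers, layer_aggregation = layer_aggregation,
                 pool = pool, n_layers = length(layers)),
            class = "gnn_architecture")
}

#' @export
print.gnn_architecture <- function(x, ...) {
  cap <- function(s) paste0(toupper(substring(s, 1, 1)), substring(s, 2))
  row <- function(f) paste(vapply(x$layers, function(l) cap(l[[f]]),
                                  character(1)), collapse = ", ")
  cat("Searched GNN architecture (", x$n_layers, " layers)\n", sep = "")
  cat("  Agg:              ", row("aggregate"), "\n")
  cat("  Combine:          ", row("combine"), "\n")
  cat("  Activation:       ", row("activation"), "\n")
  cat("  Layer Connect:    ", row("connect"), "\n")
  cat("  Layer Aggregation:", cap(x$layer_aggregation), "\n")
  cat("  Pool:             ", cap(x$pool), "\n")
  invisible(x)
}

#' Export an architecture as human-readable JSON
#'
#' @param arch A `gnn_architecture`.
#' @param path Output path.
#' @export
write_architecture <- function(arch, path) {
  jsonlite::write_json(
    list(format_version = 1L,
         n_layers = arch$n_layers,
         Agg = vapply(arch$layers, `[[`, character(1), "aggregate"),
         Combine = vapply(arch$layers, `[[`, character(1), "combine"),
         Activation = vapply(arch$layers, `[[`, character(1), "activation"),
         `Layer Connect` = vapply(arch$layers, `[[`, character(1), "connect"),
         `Layer Aggregation` = arch$layer_aggregation,
         Pool = arch$pool),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Gumbel-softmax sample over a candidate set
#'
#' `eps_o = exp((log w_o - log(-log U_o)) / tau) / sum_o' exp(...)`. The
#' output lies on the probability simplex and approaches a one-hot vector
#' at `argmax_o(log w_o - log(-log U_o))` as `tau -> 0`.
#'
#' @param w Positive operation weights.
#' @param U Uniform(0,1) draws, one per candidate.
#' @param tau Temperature (> 0).
#' @return Numeric vector summing to 1.
#' @export
gumbel_softmax_sample <- function(w, U, tau) {
  stopifnot(length(w) == length(U), tau > 0)
  if (any(w <= 0)) stop("operation weights must be positive")
  if (any(U <= 0 | U >= 1)) stop("U draws must lie in (0, 1)")
  z <- (log(w) - log(-log(U))) / tau
  z <- z - max(z)
  exp(z) / sum(exp(z))
}

#' GNN training configuration
#'
#' @param d Hidden width (default 64).
#' @param n_layers Number of message-passing layers (default 2).
#' @param epochs Training epochs for the weight-training phase.
#' @param search_epochs Epochs for the relaxed architecture-search phase.
#' @param lr Adam learning rate.
#' @param arch_lr Adam learning rate for architecture log-weights.
#' @param tau_start,tau_end Linear annealing schedule for the
#'   Gumbel-softmax temperature during search.
#' @param val_fraction Fraction of training pairs held out during the
#'   search phase: architecture log-weights are updated on held-out
#'   gradients (first-order bi-level) while model weights follow the
#'   remaining pairs. Set to 0 for single-level joint optimisation.
#' @param weight_decay Decoupled (AdamW-style) weight decay on all model
#'   weights.
#' @param aux_relations Train the link objective on all three relation
#'   classes jointly (relation-specific heads over shared node
#'   embeddings); `FALSE` restricts supervision to the evaluated
#'   query-cancer relation.
#' @param seed Integer RNG seed.
#' @return List of class `gnn_config`.
#' @export
gnn_config <- function(d = 64, n_layers = 2, epochs = 300,
                       search_epochs = 100, lr = 0.01, arch_lr = 0.05,
                       tau_start = 1, tau_end = 0.1, val_fraction = 0.2,
                       weight_decay = 0.01, aux_relations = TRUE, seed = 1) {
  stopifnot(d >= 1, n_layers >= 1, epochs >= 1, search_epochs >= 1,
            lr > 0, tau_start >= tau_end, tau_end > 0,
            val_fraction >= 0, val_fraction < 0.5, weight_decay >= 0)
  structure(list(d = d, n_layers = n_layers, epochs = epochs,
                 search_epochs = search_epochs, lr = lr, arch_lr = arch_lr,
                 tau_start = tau_start, tau_end = tau_end,
                 val_fraction = val_fraction, weight_decay = weight_decay,
                 aux_relations = isTRUE(aux_relations), seed = seed),
            class = "gnn_config")
}

# ---- standalone operations (also used inside the trainer) -----------------

#' Project per-type node attributes to the hidden width (layer-0 states)
#'
#' Bias-free type-specific linear projection, so a zero attribute vector
#' maps to a zero initial state.
#'
#' @param features Named list of per-type feature matrices (rows = nodes).
#' @param d Hidden width.
#' @param weights Optional named list of projection matrices (one per
#'   type, `ncol(features[[t]]) x d`); drawn at random when omitted.
#' @param seed Seed used when `weights` is omitted.
#' @return Named list of `n x d` state matrices; the projection maps are
#'   attached as attribute `"weights"`.
#' @export
init_node_states <- function(features, d, weights = NULL, seed = 1) {
  stopifnot(is.list(features), d >= 1)
  if (is.null(weights)) {
    restore <- local_seed(seed); on.exit(restore())
    weights <- lapply(features, function(f)
      glorot(ncol(f), d))
  }
  out <- Map(function(f, w) unname(as.matrix(f) %*% w), features, weights)
  attr(out, "weights") <- weights
  out
}

glorot <- function(fin, fout) {
  matrix(rnorm(fin * fout, sd = sqrt(2 / (fin + fout))), fin, fout)
}

# neighbour index list from a (sparse) symmetric adjacency
adj_neighbors <- function(adj) {
  n <- nrow(adj)
  am <- as(adj, "TsparseMatrix")
  nl <- split(am@j + 1L, factor(am@i + 1L, levels = seq_len(n)))
  lapply(nl, as.integer)
}

#' One intra-layer message-passing step
#'
#' Neighbour messages `W_neigh H_u` are aggregated with the chosen
#' operation, combined with the transformed self state `W_self H_v`
#' (elementwise sum, or concatenation projected back to the hidden width by
#' `W_comb`), and passed through the activation. Empty neighbourhoods
#' contribute a zero message.
#'
#' @param H Node state matrix (`n x d_in`).
#' @param adj Symmetric adjacency matrix (dense or `Matrix` sparse).
#' @param choice List with `aggregate` (`sum`/`max`/`mean`), `combine`
#'   (`sum`/`concat`), `activation` (`relu`/`prelu`).
#' @param weights List with `W_self`, `W_neigh` (`d_in x d`), `W_comb`
#'   (`2d x d`, required for `combine = "concat"`), and `prelu` slope
#'   (default 0.25).
#' @return Updated `n x d` state matrix.
#' @export
mpnn_layer <- function(H, adj, choice, weights) {
  tape <- ad_tape()
  h <- ad_const(tape, H)
  out <- mpnn_layer_node(tape, h, prep_adjacency(adj), choice,
                         list(self = ad_const(tape, weights$W_self),
                              neigh = ad_const(tape, weights$W_neigh),
                              comb = if (!is.null(weights$W_comb))
                                ad_const(tape, weights$W_comb),
                              prelu = ad_const(tape,
                                weights$prelu %||% 0.25)))
  out$value
}

`%||%` <- function(a, b) if (is.null(a)) b else a

prep_adjacency <- function(adj) {
  # force general (non-symmetric) storage so the triplet form carries
  # every neighbour, not just one triangle
  adj <- as(as(Matrix::Matrix(adj, sparse = TRUE), "generalMatrix"),
            "CsparseMatrix")
  deg <- Matrix::rowSums(adj)
  dinv <- ifelse(deg > 0, 1 / deg, 0)
  list(A = adj, DinvA = Matrix::Diagonal(x = dinv) %*% adj,
       nlist = adj_neighbors(adj))
}

# choice entries may be character (discrete) or epsilon nodes (relaxed)
mpnn_layer_node <- function(tape, h, adjp, choice, w) {
  m <- ad_mm(tape, h, w$neigh)
  agg_of <- function(op) switch(op,
    sum = ad_mm(tape, adjp$A, m),
    mean = ad_mm(tape, adjp$DinvA, m),
    max = ad_neigh_max(tape, m, adjp$nlist))
  x <- pick_or_mix(tape, c("sum", "max", "mean"), choice$aggregate, agg_of)
  s <- ad_mm(tape, h, w$self)
  comb_of <- function(op) switch(op,
    sum = ad_add(tape, s, x),
    concat = ad_mm(tape, ad_concat_cols(tape, s, x), w$comb))
  c_ <- pick_or_mix(tape, c("sum", "concat"), choice$combine, comb_of)
  act_of <- function(op) switch(op,
    relu = ad_relu(tape, c_),
    prelu = ad_prelu(tape, c_, w$prelu))
  pick_or_mix(tape, c("relu", "prelu"), choice$activation, act_of)
}

# Discrete choice (character): evaluate one candidate. Relaxed choice
# (epsilon node): evaluate all candidates and mix.
pick_or_mix <- function(tape, candidates, choice, builder) {
  if (is.character(choice)) return(builder(choice))
  ad_mix(tape, lapply(candidates, builder), choice)
}

#' Inter-layer connectivity
#'
#' `stack` passes the layer output unchanged, `skip_sum` adds the previous
#' layer's states, `skip_concat` concatenates them and projects back to the
#' hidden width with `W`.
#'
#' @param H_prev,H_k Previous and current state matrices.
#' @param choice `"stack"`, `"skip_sum"` or `"skip_concat"`.
#' @param W Projection (`2d x d`) for `skip_concat`.
#' @return Connected state matrix.
#' @export
layer_connect <- function(H_prev, H_k, choice = c("stack", "skip_sum",
                                                  "skip_concat"),
                          W = NULL) {
  choice <- match.arg(choice)
  tape <- ad_tape()
  out <- connect_node(tape, ad_const(tape, H_prev), ad_const(tape, H_k),
                      choice, if (!is.null(W)) ad_const(tape, W))
  out$value
}

connect_node <- function(tape, hp, hk, choice, w_sc) {
  build <- function(op) switch(op,
    stack = hk,
    skip_sum = {
      if (!identical(dim(hp$value), dim(hk$value)))
        stop("skip_sum requires equal widths")
      ad_add(tape, hp, hk)
    },
    skip_concat = ad_mm(tape, ad_concat_cols(tape, hp, hk), w_sc))
  pick_or_mix(tape, c("stack", "skip_sum", "skip_concat"), choice, build)
}

#' Layer aggregation across message-passing layers
#'
#' `last` (and its alias `none`) returns the final layer, `concat`
#' concatenates all layers column-wise, `max` takes the elementwise max.
#'
#' @param H_list List of per-layer state matrices `H^1 .. H^L`.
#' @param choice One of `last`, `concat`, `max`, `none`.
#' @return Aggregated state matrix.
#' @export
layer_aggregate <- function(H_list, choice = c("last", "concat", "max",
                                               "none")) {
  choice <- match.arg(choice)
  tape <- ad_tape()
  nodes <- lapply(H_list, ad_const, tape = tape)
  layer_agg_node(tape, nodes, choice)$value
}

layer_agg_node <- function(tape, nodes, choice) {
  L <- length(nodes)
  build <- function(op) switch(op,
    last = nodes[[L]],
    none = nodes[[L]],
    concat = Reduce(function(a, b) ad_concat_cols(tape, a, b), nodes),
    max = Reduce(function(a, b) ad_emax(tape, a, b), nodes))
  if (is.character(choice)) return(build(choice))
  ad_mix(tape, lapply(c("last", "concat", "max", "none"), build), choice)
}

#' Edge readout: pool the two endpoint embeddings
#'
#' @param H Final node state matrix.
#' @param pair Integer vector `c(query_row, cancer_row)` of endpoint rows.
#' @param pool `"sum"`, `"max"` (elementwise) or `"concat"` (query first).
#' @return Edge embedding vector `H_e`.
#' @export
edge_readout <- function(H, pair, pool = c("sum", "max", "concat")) {
  pool <- match.arg(pool)
  stopifnot(length(pair) == 2, all(pair >= 1), all(pair <= nrow(H)))
  q <- H[pair[1], ]
  c_ <- H[pair[2], ]
  switch(pool, sum = q + c_, max = pmax(q, c_), concat = c(q, c_))
}

pool_node <- function(tape, hq, hc, choice) {
  build <- function(op) switch(op,
    sum = ad_add(tape, hq, hc),
    max = ad_emax(tape, hq, hc),
    concat = ad_concat_cols(tape, hq, hc))
  if (is.character(choice)) return(build(choice))
  stop("pool mixing is handled at the score level")  # see gnn_forward
}

#' Pearson similarity matrix between edge embeddings
#'
#' @param table Matrix of edge embeddings, one row per pair (rownames used
#'   as labels).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
embedding_similarity_matrix <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2) stop("need at least 2 edge embeddings")
  sdev <- apply(table, 1, sd)
  if (any(sdev == 0))
    stop("zero-variance edge embedding(s): row(s) ",
         paste(which(sdev == 0), collapse = ", "),
         "; Pearson correlation undefined")
  r <- cor(t(table))
  diag(r) <- 1
  r
}

# ---- model assembly and training ------------------------------------------

# Precompute everything the forward pass needs from a network + features.
gnn_prepare <- function(net, features) {
  stopifnot(inherits(net, "hetnet"), is.list(features))
  types <- intersect(HET_NODE_TYPES, unique(net$nodes$type))
  stopifnot(all(types %in% names(features)))
  # rows of each type's feature matrix must align with network node order
  feats <- lapply(types, function(ty) {
    f <- as.matrix(features[[ty]])
    ids <- het_nodes_of_type(net, ty)
    stopifnot(identical(rownames(f), ids))
    f
  })
  names(feats) <- types
  list(net = net, types = types, features = feats,
       adjp = prep_adjacency(het_adjacency(net)))
}

gnn_init_params <- function(prep, cfg) {
  d <- cfg$d
  L <- cfg$n_layers
  p <- list()
  for (ty in prep$types)
    p[[paste0("proj_", ty)]] <- glorot(ncol(prep$features[[ty]]), d)
  for (k in seq_len(L)) {
    p[[paste0("l", k, "_self")]] <- glorot(d, d)
    p[[paste0("l", k, "_neigh")]] <- glorot(d, d)
    p[[paste0("l", k, "_comb")]] <- glorot(2 * d, d)
    p[[paste0("l", k, "_sc")]] <- glorot(2 * d, d)
    p[[paste0("l", k, "_prelu")]] <- 0.25
  }
  for (rel in names(HET_RELATIONS)) {
    for (agg in c("last", "concat", "max", "none")) {
      base <- if (agg == "concat") L * d else d
      p[[paste0("headdot_", rel, "_", agg)]] <- rep(1 / sqrt(base), base)
      for (pool in c("sum", "max", "concat")) {
        dim_in <- if (pool == "concat") 2 * base else base
        p[[paste0("head_", rel, "_", agg, "_", pool)]] <- glorot(dim_in, 1)
        p[[paste0("headb_", rel, "_", agg, "_", pool)]] <- 0
      }
    }
  }
  p
}

gnn_arch_logits_init <- function(cfg) {
  sp <- search_space()
  a <- list()
  for (k in seq_len(cfg$n_layers)) {
    a[[paste0("alpha_aggregate_l", k)]] <- numeric(length(sp$aggregate))
    a[[paste0("alpha_combine_l", k)]] <- numeric(length(sp$combine))
    a[[paste0("alpha_activation_l", k)]] <- numeric(length(sp$activation))
    a[[paste0("alpha_connect_l", k)]] <- numeric(length(sp$connect))
  }
  a$alpha_layer_aggregation <- numeric(length(sp$layer_aggregation))
  a$alpha_pool <- numeric(length(sp$pool))
  a
}

# Node-embedding part of the forward pass: per-layer states under the
# given choices. `choices` holds per-decision selections: character for
# discrete, epsilon nodes for relaxed search.
gnn_node_layers <- function(tape, prep, pn, choices, cfg) {
  h <- ad_concat_rows(tape, lapply(prep$types, function(ty)
    ad_mm(tape, ad_const(tape, prep$features[[ty]]),
          pn[[paste0("proj_", ty)]])))
  layers <- list()
  for (k in seq_len(cfg$n_layers)) {
    w <- list(self = pn[[paste0("l", k, "_self")]],
              neigh = pn[[paste0("l", k, "_neigh")]],
              comb = pn[[paste0("l", k, "_comb")]],
              prelu = pn[[paste0("l", k, "_prelu")]])
    hk <- mpnn_layer_node(tape, h, prep$adjp,
                          list(aggregate = choices$layers[[k]]$aggregate,
                               combine = choices$layers[[k]]$combine,
                               activation = choices$layers[[k]]$activation),
                          w)
    hk <- connect_node(tape, h, hk, choices$layers[[k]]$connect,
                       pn[[paste0("l", k, "_sc")]])
    layers[[k]] <- hk
    h <- hk
  }
  layers
}

# Readout + scoring of one endpoint-index batch against one relation's
# heads. Layer aggregation and pooling change the embedding width, so in
# relaxed mode those two decisions mix at the score level (one linear head
# per combination).
gnn_score_pairs <- function(tape, pn, layers, q_idx, c_idx, choices, rel) {
  agg_choice <- choices$layer_aggregation
  pool_choice <- choices$pool
  score_of <- function(agg, pool) {
    hh <- layer_agg_node(tape, layers, agg)
    hq <- ad_rows(tape, hh, q_idx)
    hc <- ad_rows(tape, hh, c_idx)
    he <- pool_node(tape, hq, hc, pool)
    # linear head on the pooled edge embedding plus a diagonal bilinear
    # decoder term <H_q, diag(s) H_c>: sum/concat pooling alone is
    # additive in the endpoints and cannot express endpoint affinity
    z <- ad_mm(tape, he, pn[[paste0("head_", rel, "_", agg, "_", pool)]])
    z <- ad_add_bias(tape, z,
                     pn[[paste0("headb_", rel, "_", agg, "_", pool)]])
    dot <- ad_rowdot(tape,
                     ad_colscale(tape, hq,
                                 pn[[paste0("headdot_", rel, "_", agg)]]),
                     hc)
    z <- ad_add(tape, z, dot)
    list(he = he, z = z)
  }
  if (is.character(agg_choice) && is.character(pool_choice)) {
    out <- score_of(agg_choice, pool_choice)
    return(list(logits = out$z, he = out$he))
  }
  sp <- search_space()
  terms <- list()
  for (i in seq_along(sp$layer_aggregation)) {
    for (j in seq_along(sp$pool)) {
      z <- score_of(sp$layer_aggregation[i], sp$pool[j])$z
      e <- ad_smul(tape, ad_elem(tape, agg_choice, i),
                   ad_elem(tape, pool_choice, j))
      terms[[length(terms) + 1L]] <- ad_scale_by(tape, z, e)
    }
  }
  list(logits = Reduce(function(a, b) ad_add(tape, a, b), terms),
       he = NULL)
}

# Full forward to logits for one relation's batch.
gnn_forward <- function(tape, prep, pn, q_idx, c_idx, choices, cfg,
                        rel = "circ_cancer") {
  layers <- gnn_node_layers(tape, prep, pn, choices, cfg)
  gnn_score_pairs(tape, pn, layers, q_idx, c_idx, choices, rel)
}

# Split positive/negative pair indices into a weight-training part and a
# held-out part (used for checkpoint selection and, during search, for the
# architecture-gradient updates).
holdout_split <- function(pairs_idx, frac) {
  npos <- nrow(pairs_idx$pos)
  nneg <- nrow(pairs_idx$neg)
  if (frac <= 0 || npos < 5 || nneg < 5)
    return(list(train = pairs_idx, val = NULL))
  vp <- sample.int(npos, max(1, round(frac * npos)))
  vn <- sample.int(nneg, max(1, round(frac * nneg)))
  list(train = list(pos = pairs_idx$pos[-vp, , drop = FALSE],
                    neg = pairs_idx$neg[-vn, , drop = FALSE]),
       val = list(pos = pairs_idx$pos[vp, , drop = FALSE],
                  neg = pairs_idx$neg[vn, , drop = FALSE]))
}

# One training epoch over all relation batches: for each relation,
# balanced BCE of its positive pairs against freshly sampled unobserved
# pairs (1:1); the epoch loss is the mean over relations. Multi-source
# supervision: every relation class contributes link gradients to the
# shared node embeddings, only the heads are relation-specific.
gnn_epoch <- function(prep, params, arch_logits, batches, cfg, tau,
                      relaxed) {
  tape <- ad_tape()
  pn <- ad_wrap_params(tape, params)
  an <- if (relaxed) ad_wrap_params(tape, arch_logits)
  choices <- if (relaxed) {
    eps_of <- function(name, k) {
      key <- paste0("alpha_", name, if (!is.null(k)) paste0("_l", k))
      nk <- length(an[[key]]$value)
      g <- -log(-log(runif(nk)))
      ad_gumbel_softmax(tape, an[[key]], g, tau)
    }
    list(layers = lapply(seq_len(cfg$n_layers), function(k) list(
           aggregate = eps_of("aggregate", k),
           combine = eps_of("combine", k),
           activation = eps_of("activation", k),
           connect = eps_of("connect", k))),
         layer_aggregation = eps_of("layer_aggregation", NULL),
         pool = eps_of("pool", NULL))
  } else {
    arch_logits  # a gnn_architecture in discrete mode
  }
  layers <- gnn_node_layers(tape, prep, pn, choices, cfg)
  losses <- list()
  for (b in batches) {
    take <- b$neg[sample.int(nrow(b$neg), min(nrow(b$pos), nrow(b$neg))), ,
                  drop = FALSE]
    batch <- rbind(b$pos, take)
    y <- c(rep(1, nrow(b$pos)), rep(0, nrow(take)))
    sc <- gnn_score_pairs(tape, pn, layers, batch[, 1], batch[, 2],
                          choices, b$rel)
    losses[[length(losses) + 1L]] <- ad_bce_logits(tape, sc$logits, y)
  }
  total <- Reduce(function(a, b) ad_add(tape, a, b), losses)
  loss <- ad_scale_by(tape, total, ad_const(tape, 1 / length(losses)))
  if (!is.finite(loss$value))
    stop("training diverged: non-finite loss")
  ad_backward(tape, loss)
  grads <- lapply(pn, function(n) n$grad)
  agrads <- if (relaxed) lapply(an, function(n) n$grad)
  list(loss = loss$value, grads = grads, agrads = agrads)
}

# Positive/negative endpoint-index matrices for a non-evaluated relation,
# taken directly from the (already test-masked) network.
relation_pairs_idx <- function(prep, rel) {
  ty <- HET_RELATIONS[[rel]]
  rows <- which(prep$net$nodes$type == ty[1])
  cols <- which(prep$net$nodes$type == ty[2])
  e <- prep$net$edges[prep$net$edges$relation == rel, , drop = FALSE]
  grid <- cbind(rep(rows, times = length(cols)),
                rep(cols, each = length(rows)))
  key <- paste(grid[, 1], grid[, 2])
  ekey <- paste(e$source_idx, e$target_idx)
  is_pos <- key %in% ekey
  list(rel = rel, pos = grid[is_pos, , drop = FALSE],
       neg = grid[!is_pos, , drop = FALSE])
}

# Assemble per-relation training batches: the evaluated relation from the
# candidate-pair split (negatives exclude held-out pairs), the other
# relations straight from the network.
gnn_batches <- function(prep, pairs_idx, query_type, aux) {
  eval_rel <- relation_for_query(query_type)
  batches <- list(c(list(rel = eval_rel), pairs_idx))
  if (aux) {
    for (rel in setdiff(names(HET_RELATIONS), eval_rel)) {
      b <- relation_pairs_idx(prep, rel)
      if (nrow(b$pos) > 0 && nrow(b$neg) > 0)
        batches[[length(batches) + 1L]] <- b
    }
  }
  batches
}

pairs_to_idx <- function(prep, pairs, query_type) {
  net <- prep$net
  qk <- node_key(query_type, pairs$query_id)
  ck <- node_key("cancer", pairs$cancer_id)
  if (anyNA(net$index[qk]) || anyNA(net$index[ck]))
    stop("candidate pair references a node absent from the network")
  cbind(unname(net$index[qk]), unname(net$index[ck]))
}

# Split candidate pairs into positive / negative endpoint-index matrices.
split_pos_neg <- function(prep, pairs, query_type) {
  idx <- pairs_to_idx(prep, pairs, query_type)
  list(pos = idx[pairs$label == 1, , drop = FALSE],
       neg = idx[pairs$label == 0, , drop = FALSE])
}

#' Train the GNN under a fixed (discrete) architecture
#'
#' Full-batch Adam on a balanced binary cross-entropy link objective:
#' observed training pairs against an equal number of unobserved pairs
#' resampled each epoch.
#'
#' @param net Training `hetnet` (test edges already masked).
#' @param features Per-type node attribute features
#'   ([node_attribute_features()]), computed from the same training
#'   network.
#' @param pairs Training `candidate_pairs` (positives and candidate
#'   negatives).
#' @param arch A `gnn_architecture`.
#' @param cfg A `gnn_config`.
#' @param query_type `"circRNA"` or `"drug"`.
#' @return A `gnn_fit`: architecture, trained parameters, loss trajectory
#'   and the prepared graph (for deterministic embedding).
#' @export
gnn_train <- function(net, features, pairs, arch, cfg = gnn_config(),
                      query_type = c("circRNA", "drug")) {
  query_type <- match.arg(query_type)
  stopifnot(inherits(arch, "gnn_architecture"),
            arch$n_layers == cfg$n_layers)
  prep <- gnn_prepare(net, features)
  restore <- local_seed(cfg$seed); on.exit(restore())
  params <- gnn_init_params(prep, cfg)
  st <- adam_state(params)
  pairs_idx <- split_pos_neg(prep, pairs, query_type)
  if (nrow(pairs_idx$pos) == 0) stop("no positive training pairs")
  batches <- gnn_batches(prep, pairs_idx, query_type, cfg$aux_relations)
  losses <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    res <- gnn_epoch(prep, params, arch, batches, cfg, tau = 1,
                     relaxed = FALSE)
    losses[ep] <- res$loss
    upd <- adam_step(params, res$grads, st, lr = cfg$lr,
                     weight_decay = cfg$weight_decay)
    params <- upd$params
    st <- upd$state
  }
  structure(list(arch = arch, params = params, cfg = cfg,
                 prep = prep, query_type = query_type, losses = losses),
            class = "gnn_fit")
}

#' Search the architecture, then retrain it from scratch
#'
#' Phase 1 jointly optimises architecture log-weights and model weights on
#' the relaxed (Gumbel-softmax mixed) model while annealing the temperature
#' linearly from `tau_start` to `tau_end`; the discrete architecture is the
#' per-decision argmax of the learned log-weights. Phase 2 retrains model
#' weights from scratch under the discrete architecture.
#'
#' @inheritParams gnn_train
#' @param space A `search_space` (only the default is supported).
#' @return List with `arch` (the selected `gnn_architecture`), `fit`
#'   (retrained `gnn_fit`), `arch_logits`, and `search_losses`.
#' @export
gnn_search <- function(net, features, pairs, space = search_space(),
                       cfg = gnn_config(),
                       query_type = c("circRNA", "drug")) {
  query_type <- match.arg(query_type)
  prep <- gnn_prepare(net, features)
  restore <- local_seed(cfg$seed); on.exit(restore())
  params <- gnn_init_params(prep, cfg)
  alphas <- gnn_arch_logits_init(cfg)
  st <- adam_state(params)
  sa <- adam_state(alphas)
  pairs_idx <- split_pos_neg(prep, pairs, query_type)
  if (nrow(pairs_idx$pos) == 0) stop("no positive training pairs")
  sp <- holdout_split(pairs_idx, cfg$val_fraction)
  train_batches <- gnn_batches(prep, sp$train, query_type,
                               cfg$aux_relations)
  val_batches <- if (!is.null(sp$val))
    gnn_batches(prep, sp$val, query_type, cfg$aux_relations)
  losses <- numeric(cfg$search_epochs)
  for (ep in seq_len(cfg$search_epochs)) {
    frac <- if (cfg$search_epochs == 1) 1 else (ep - 1) / (cfg$search_epochs - 1)
    tau <- cfg$tau_start + frac * (cfg$tau_end - cfg$tau_start)
    res <- gnn_epoch(prep, params, alphas, train_batches, cfg, tau,
                     relaxed = TRUE)
    losses[ep] <- res$loss
    upd <- adam_step(params, res$grads, st, lr = cfg$lr,
                     weight_decay = cfg$weight_decay)
    params <- upd$params; st <- upd$state
    # architecture gradients from the held-out pairs when available
    # (first-order bi-level); otherwise single-level joint optimisation
    ares <- if (is.null(val_batches)) res
    else gnn_epoch(prep, params, alphas, val_batches, cfg, tau,
                   relaxed = TRUE)
    upd <- adam_step(alphas, ares$agrads, sa, lr = cfg$arch_lr)
    alphas <- upd$params; sa <- upd$state
  }
  sp <- search_space()
  pick <- function(name, k = NULL) {
    key <- paste0("alpha_", name, if (!is.null(k)) paste0("_l", k))
    sp[[name]][which.max(alphas[[key]])]
  }
  arch <- gnn_architecture(
    layers = lapply(seq_len(cfg$n_layers), function(k) list(
      aggregate = pick("aggregate", k), combine = pick("combine", k),
      activation = pick("activation", k), connect = pick("connect", k))),
    layer_aggregation = pick("layer_aggregation"),
    pool = pick("pool"))
  fit <- gnn_train(net, features, pairs, arch, cfg, query_type)
  list(arch = arch, fit = fit, arch_logits = alphas,
       search_losses = losses)
}

#' Edge embeddings (and link scores) for candidate pairs
#'
#' Deterministic forward pass of a trained model; the edge embedding of a
#' pair is the pooled endpoint representation `H_e`, and the score is the
#' trained linear head applied to it.
#'
#' @param fit A `gnn_fit`.
#' @param pairs `candidate_pairs` to embed (must reference nodes of the
#'   fitted network).
#' @return List with `embeddings` (matrix, one row per pair, rownames
#'   `"query|cancer"`) and `scores`.
#' @export
embed_edges <- function(fit, pairs) {
  stopifnot(inherits(fit, "gnn_fit"))
  tape <- ad_tape()
  pn <- ad_wrap_params(tape, fit$params)
  idx <- pairs_to_idx(fit$prep, pairs, fit$query_type)
  fwd <- gnn_forward(tape, fit$prep, pn, idx[, 1], idx[, 2], fit$arch,
                     fit$cfg, rel = relation_for_query(fit$query_type))
  emb <- fwd$he$value
  rownames(emb) <- paste(pairs$query_id, pairs$cancer_id, sep = "|")
  list(embeddings = emb, scores = as.numeric(fwd$logits$value))
}

#' Serialize / restore a trained GNN checkpoint as JSON
#'
#' The checkpoint stores the discrete architecture, training configuration
#' and all weight matrices. Restoring additionally needs the network and
#' features the model was trained on (they define node order and input
#' dimensions and are not duplicated into the checkpoint).
#'
#' @param fit A `gnn_fit`.
#' @param path File path.
#' @export
write_gnn_checkpoint <- function(fit, path) {
  jsonlite::write_json(
    list(format_version = 1L,
         arch = list(layers = fit$arch$layers,
                     layer_aggregation = fit$arch$layer_aggregation,
                     pool = fit$arch$pool),
         cfg = unclass(fit$cfg),
         query_type = fit$query_type,
         params = lapply(fit$params, function(p)
           list(dim = dim(p) %||% length(p), data = as.numeric(p)))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gnn_checkpoint
#' @param net,features The training network and features (see
#'   [gnn_train()]).
#' @export
read_gnn_checkpoint <- function(path, net, features) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(obj$format_version == 1L)
  layers <- lapply(seq_len(nrow(obj$arch$layers)), function(i)
    as.list(obj$arch$layers[i, ]))
  arch <- gnn_architecture(layers, obj$arch$layer_aggregation,
                           obj$arch$pool)
  cfg <- do.call(gnn_config, obj$cfg)
  params <- lapply(obj$params, function(p) {
    v <- as.numeric(p$data)
    if (length(p$dim) == 2) matrix(v, p$dim[1], p$dim[2]) else v
  })
  structure(list(arch = arch, params = params, cfg = cfg,
                 prep = gnn_prepare(net, features),
                 query_type = obj$query_type, losses = NULL),
            class = "gnn_fit")
}
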