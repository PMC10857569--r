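test_that("mpnn_layer reproduces the path-graph hand computation", {
  # a-b-c path, 1-dim states (1,2,3), identity maps, sum/sum/relu
  adj <- matrix(c(0, 1, 0,
                  1, 0, 1,
                  0, 1, 0), 3, byrow = TRUE)
  H <- matrix(c(1, 2, 3), ncol = 1)
  out <- mpnn_layer(H, adj,
                    choice = list(aggregate = "sum", combine = "sum",
                                  activation = "relu"),
                    weights = list(W_self = diag(1), W_neigh = diag(1)))
  expect_equal(as.numeric(out), c(3, 6, 5))
})

test_that("mpnn_layer equals the explicit-loop oracle for all intra-layer
           operation combinations", {
  set.seed(21)
  sp <- search_space()
  for (rep in 1:2) {
    n <- 20
    din <- 3
    d <- 4
    adj <- random_adjacency(n, 0.25)
    H <- matrix(rnorm(n * din), n, din)
    W_self <- matrix(rnorm(din * d), din, d)
    W_neigh <- matrix(rnorm(din * d), din, d)
    W_comb <- matrix(rnorm(2 * d * d), 2 * d, d)
    for (agg in sp$aggregate) for (comb in sp$combine)
      for (act in sp$activation) {
        got <- mpnn_layer(H, adj,
                          choice = list(aggregate = agg, combine = comb,
                                        activation = act),
                          weights = list(W_self = W_self,
                                         W_neigh = W_neigh,
                                         W_comb = W_comb, prelu = 0.25))
        want <- mpnn_oracle(H, adj, agg, comb, act, W_self, W_neigh,
                            W_comb, prelu = 0.25)
        expect_equal(got, want, tolerance = 1e-10,
                     label = paste(agg, comb, act))
      }
  }
})

test_that("mpnn_layer handles isolated nodes and ignores node labels", {
  set.seed(4)
  adj <- random_adjacency(10, 0.3)
  adj[1, ] <- 0; adj[, 1] <- 0  # isolate node 1
  H <- matrix(rnorm(20), 10, 2)
  W <- list(W_self = diag(2), W_neigh = matrix(rnorm(4), 2, 2))
  for (agg in c("sum", "max", "mean")) {
    out <- mpnn_layer(H, adj, list(aggregate = agg, combine = "sum",
                                   activation = "relu"), W)
    # empty neighbourhood -> combine reduces to the self term
    expect_equal(out[1, ], pmax(as.numeric(H[1, ] %*% W$W_self), 0))
    # relabeling (permuting) nodes commutes with the layer
    p <- sample(10)
    out_p <- mpnn_layer(H[p, ], adj[p, p],
                        list(aggregate = agg, combine = "sum",
                             activation = "relu"), W)
    expect_equal(out_p, out[p, ], tolerance = 1e-10)
  }
})

test_that("layer connectivity operations follow their definitions", {
  H0 <- matrix(1, 2, 3)
  H1 <- matrix(2, 2, 3)
  expect_equal(layer_connect(H0, H1, "stack"), H1)
  expect_equal(layer_connect(H0, H1, "skip_sum"), H0 + H1)
  # skip_concat with W = rbind(I, I) equals skip_sum
  W <- rbind(diag(3), diag(3))
  expect_equal(layer_connect(H0, H1, "skip_concat", W),
               layer_connect(H0, H1, "skip_sum"), tolerance = 1e-12)
  expect_error(layer_connect(matrix(1, 2, 2), H1, "skip_sum"),
               "equal widths")
})

test_that("layer aggregation covers last/concat/max/none", {
  H1 <- matrix(c(1, 5), 1)
  H2 <- matrix(c(3, 2), 1)
  expect_equal(layer_aggregate(list(H1), "concat"), H1)
  expect_equal(layer_aggregate(list(H1, H2), "last"), H2)
  expect_equal(layer_aggregate(list(H1, H2), "none"), H2)
  expect_equal(layer_aggregate(list(H1, H2), "max"), matrix(c(3, 5), 1))
  expect_equal(ncol(layer_aggregate(list(H1, H2), "concat")), 4)
})

test_that("edge readout pools endpoint embeddings", {
  H <- rbind(c(1, 0), c(0, 1))
  expect_equal(edge_readout(H, c(1, 2), "sum"), c(1, 1))
  expect_equal(edge_readout(H, c(1, 2), "max"), c(1, 1))
  expect_equal(edge_readout(H, c(2, 1), "sum"),
               edge_readout(H, c(1, 2), "sum"))
  # concat is order-sensitive: query first
  expect_equal(edge_readout(H, c(1, 2), "concat"), c(1, 0, 0, 1))
  expect_false(isTRUE(all.equal(edge_readout(H, c(2, 1), "concat"),
                                edge_readout(H, c(1, 2), "concat"))))
  expect_equal(edge_readout(H, c(1, 1), "max"), H[1, ])
  expect_error(edge_readout(H, c(1, 5), "sum"))
})

test_that("gumbel_softmax_sample lies on the simplex with the tau limits", {
  set.seed(9)
  for (i in 1:20) {
    w <- runif(4, 0.1, 5)
    U <- runif(4)
    eps <- gumbel_softmax_sample(w, U, tau = runif(1, 0.1, 3))
    expect_equal(sum(eps), 1, tolerance = 1e-9)
    expect_true(all(eps >= 0))
  }
  # equal weights, equal draws -> uniform
  expect_equal(gumbel_softmax_sample(rep(2, 5), rep(0.3, 5), 1),
               rep(1 / 5, 5))
  # tau -> 0: one-hot at argmax(log w - log(-log U))
  w <- c(0.5, 2, 1.2)
  U <- c(0.9, 0.2, 0.6)
  hard <- gumbel_softmax_sample(w, U, tau = 1e-4)
  arg <- which.max(log(w) - log(-log(U)))
  expect_equal(hard[arg], 1, tolerance = 1e-6)
  expect_true(all(hard[-arg] < 1e-6))
  expect_error(gumbel_softmax_sample(c(-1, 2), c(0.5, 0.5), 1), "positive")
  # at small tau the sample concentrates on the argmax, whose
  # distribution is softmax(log w) (Gumbel-max), so the expectation over
  # draws tracks the normalised weights within Monte-Carlo error
  set.seed(10)
  m <- rowMeans(vapply(1:4000, function(i)
    gumbel_softmax_sample(w, runif(3), 0.05), numeric(3)))
  expect_equal(m, w / sum(w), tolerance = 0.03)
})

test_that("initial node states are bias-free typed projections", {
  feats <- list(circRNA = matrix(c(0, 0, 1, 2), 2, 2, byrow = TRUE,
                                 dimnames = list(c("r1", "r2"), NULL)),
                cancer = matrix(1, 3, 5,
                                dimnames = list(paste0("c", 1:3), NULL)))
  st <- init_node_states(feats, d = 4, seed = 2)
  expect_equal(dim(st$circRNA), c(2, 4))
  expect_equal(dim(st$cancer), c(3, 4))
  # zero feature vector -> zero initial state
  expect_equal(st$circRNA[1, ], rep(0, 4))
  # identical feature vectors -> identical states
  expect_equal(st$cancer[1, ], st$cancer[2, ])
})

test_that("search returns a valid architecture and training learns the
           planted links", {
  sim <- generate_hetnet(synthetic_config(n_circ = 24, n_drug = 8,
                                          n_cancer = 10, seed = 6))
  feats <- node_attribute_features(sim$net, task = "circRNA",
                                   scope = "all")
  pairs <- enumerate_candidate_pairs(sim$net, "circRNA")
  cfg <- gnn_config(d = 16, epochs = 120, search_epochs = 40, seed = 3)
  sr <- gnn_search(sim$net, feats, pairs, cfg = cfg)
  sp <- search_space()
  for (l in sr$arch$layers) {
    expect_true(l$aggregate %in% sp$aggregate)
    expect_true(l$combine %in% sp$combine)
    expect_true(l$activation %in% sp$activation)
    expect_true(l$connect %in% sp$connect)
  }
  expect_true(sr$arch$layer_aggregation %in% sp$layer_aggregation)
  expect_true(sr$arch$pool %in% sp$pool)
  # training AUC on the planted network is high
  emb <- embed_edges(sr$fit, pairs)
  expect_gte(auc(pairs$label, emb$scores), 0.9)
})

test_that("edge embeddings are deterministic with documented widths", {
  sim <- generate_hetnet(synthetic_config(n_circ = 15, n_drug = 6,
                                          n_cancer = 8, seed = 2))
  feats <- node_attribute_features(sim$net, task = "circRNA")
  pairs <- enumerate_candidate_pairs(sim$net, "circRNA")
  cfg <- gnn_config(d = 8, epochs = 15, search_epochs = 5, seed = 1)
  for (spec in list(list(agg = "last", pool = "sum", width = 8),
                    list(agg = "concat", pool = "max", width = 16),
                    list(agg = "concat", pool = "concat", width = 32))) {
    arch <- gnn_architecture(
      layers = rep(list(list(aggregate = "sum", combine = "sum",
                             activation = "relu", connect = "stack")), 2),
      layer_aggregation = spec$agg, pool = spec$pool)
    fit <- gnn_train(sim$net, feats, pairs, arch, cfg)
    e1 <- embed_edges(fit, pairs)
    e2 <- embed_edges(fit, pairs)
    expect_identical(e1$embeddings, e2$embeddings)
    expect_equal(ncol(e1$embeddings), spec$width)
  }
})

test_that("embedding similarity is Pearson correlation with guards", {
  x <- c(1, 2, 3)
  m <- rbind(a = x, b = x)
  expect_equal(embedding_similarity_matrix(m)["a", "b"], 1)
  m2 <- rbind(a = c(1, 2, 3), b = c(3, 2, 1))
  expect_equal(embedding_similarity_matrix(m2)["a", "b"], -1)
  m3 <- rbind(a = c(1, 2, 3), b = c(1, 2, 4))
  r <- cor(c(1, 2, 3), c(1, 2, 4))
  expect_equal(embedding_similarity_matrix(m3)["a", "b"], r,
               tolerance = 1e-10)
  expect_equal(round(r, 5), 0.98198)
  sym <- embedding_similarity_matrix(rbind(m3, c = c(5, 1, 2)))
  expect_equal(sym, t(sym))
  expect_equal(unname(diag(sym)), rep(1, 3))
  expect_error(embedding_similarity_matrix(rbind(a = c(1, 1, 1),
                                                 b = c(1, 2, 3))),
               "zero-variance")
})

test_that("checkpoints and architecture JSON round-trip", {
  sim <- generate_hetnet(synthetic_config(n_circ = 12, n_drug = 5,
                                          n_cancer = 6, seed = 8))
  feats <- node_attribute_features(sim$net, task = "circRNA")
  pairs <- enumerate_candidate_pairs(sim$net, "circRNA")
  arch <- gnn_architecture(
    layers = rep(list(list(aggregate = "max", combine = "concat",
                           activation = "prelu", connect = "skip_sum")), 2),
    layer_aggregation = "concat", pool = "max")
  fit <- gnn_train(sim$net, feats, pairs, arch,
                   gnn_config(d = 6, epochs = 10, seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_gnn_checkpoint(fit, path)
  fit2 <- read_gnn_checkpoint(path, sim$net, feats)
  e1 <- embed_edges(fit, pairs)
  e2 <- embed_edges(fit2, pairs)
  expect_equal(e1$embeddings, e2$embeddings, tolerance = 1e-12)
  expect_equal(e1$scores, e2$scores, tolerance = 1e-12)

  apath <- withr::local_tempfile(fileext = ".json")
  write_architecture(fit$arch, apath)
  obj <- jsonlite::read_json(apath, simplifyVector = TRUE)
  expect_equal(obj$Pool, "max")
  expect_equal(obj$Agg, c("max", "max"))
})
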