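test_that("RankLib lines are formatted exactly as specified", {
  ds <- ranking_dataset(label = 1, qid = "q3", did = "c7",
                        features = matrix(c(0.5, -1.25), 1))
  path <- withr::local_tempfile(fileext = ".txt")
  write_ranklib(ds, path)
  expect_equal(readLines(path), "1 qid:q3 1:0.5 2:-1.25 # did=c7")
})

test_that("RankLib round-trip is the identity on random datasets", {
  set.seed(17)
  n <- 100
  ds <- ranking_dataset(label = rbinom(n, 1, 0.3),
                        qid = sample(paste0("q", 1:8), n, replace = TRUE),
                        did = paste0("c", seq_len(n)),
                        features = matrix(rnorm(n * 5), n))
  path <- withr::local_tempfile(fileext = ".txt")
  write_ranklib(ds, path)
  back <- read_ranklib(path)
  expect_identical(back$label, ds$label)
  expect_identical(back$qid, ds$qid)
  expect_identical(back$did, ds$did)
  expect_identical(back$features, unname(ds$features))
})

test_that("RankLib parsing rejects malformed input with line numbers", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 qid:q1 1:0.5 2:0.1 # did=c1",
               "0 qid:q1 1:0.5 3:0.1 # did=c2"), path)   # gap in indices
  expect_error(read_ranklib(path), "line 2")
  writeLines("junk", path)
  expect_error(read_ranklib(path), "line 1")
  writeLines("1 qid:q1 1:zero # did=c1", path)
  expect_error(read_ranklib(path), "line 1")
})

test_that("LambdaMART solves the two-document toy problem monotonically", {
  # one query, two docs, one feature separating them
  ds <- ranking_dataset(label = c(1, 0), qid = c("q1", "q1"),
                        did = c("c1", "c2"),
                        features = matrix(c(2, 1), 2))
  cfg <- lambdamart_config(n_trees = 20, n_leaves = 2)
  model <- train_lambdamart(ds, cfg)
  pred <- predict_scores(model, ds)
  expect_gt(pred$scores[1], pred$scores[2])
  expect_equal(ndcg_at_k(pred$ranking$label, k = 1), 1)
  # training NDCG non-decreasing over boosting iterations
  ndcg_t <- vapply(seq_along(model$trees), function(t) {
    m <- model
    m$trees <- m$trees[seq_len(t)]
    p <- predict_scores(m, ds)
    ndcg_at_k(p$ranking$label)
  }, numeric(1))
  expect_true(all(diff(ndcg_t) >= -1e-12))
})

test_that("training requires at least one mixed-label query", {
  ds <- ranking_dataset(label = c(0, 0, 1, 1), qid = c("a", "a", "b", "b"),
                        did = paste0("c", 1:4), features = matrix(rnorm(8), 4))
  expect_error(train_lambdamart(ds), "relevant")
  ds0 <- ranking_dataset(label = rep(0, 4), qid = rep("a", 4),
                         did = paste0("c", 1:4),
                         features = matrix(rnorm(8), 4))
  expect_error(train_lambdamart(ds0), "relevant")
})

test_that("prediction is deterministic, rank-invariant to leaf shifts,
           and guards feature width", {
  set.seed(23)
  ds <- generate_ranking_dataset(6, 8, separation = 2, seed = 4)
  model <- train_lambdamart(ds, lambdamart_config(n_trees = 30))
  p1 <- predict_scores(model, ds)
  p2 <- predict_scores(model, ds)
  expect_identical(p1$scores, p2$scores)

  # adding a constant to every leaf of every tree preserves rankings
  shifted <- model
  shifted$trees <- lapply(shifted$trees, function(tr) {
    tr$value <- tr$value + 0.7
    tr
  })
  p3 <- predict_scores(shifted, ds)
  expect_identical(p3$ranking$did, p1$ranking$did)

  # an empty ensemble scores everything 0 and orders by did
  empty <- model
  empty$trees <- list()
  p0 <- predict_scores(empty, ds)
  expect_true(all(p0$scores == 0))
  byq <- split(p0$ranking$did, p0$ranking$qid)
  expect_true(all(vapply(byq, function(d) !is.unsorted(d), logical(1))))

  bad <- ranking_dataset(ds$label, ds$qid, ds$did, ds$features[, 1:3])
  expect_error(predict_scores(model, bad), "width")
})

test_that("scores are per-sample: duplicating a query's list changes
           nothing", {
  ds <- generate_ranking_dataset(4, 6, separation = 2, seed = 9)
  model <- train_lambdamart(ds, lambdamart_config(n_trees = 30))
  base <- predict_scores(model, ds)$scores
  dup <- ranking_dataset(c(ds$label, ds$label[1:6]),
                         c(ds$qid, rep("q_copy", 6)),
                         c(ds$did, ds$did[1:6]),
                         rbind(ds$features, ds$features[1:6, ]))
  got <- predict_scores(model, dup)$scores
  expect_equal(got[seq_along(base)], base)
  expect_equal(got[-seq_along(base)], base[1:6])
})

test_that("model JSON round-trips and reproduces predictions", {
  ds <- generate_ranking_dataset(4, 6, separation = 2, seed = 5)
  model <- train_lambdamart(ds, lambdamart_config(n_trees = 15))
  path <- withr::local_tempfile(fileext = ".json")
  write_lmart_model(model, path)
  back <- read_lmart_model(path)
  expect_equal(predict_scores(back, ds)$scores,
               predict_scores(model, ds)$scores, tolerance = 1e-12)
})

test_that("ranking quality is close to an independent boosted
           lambdarank implementation", {
  skip_if_not_installed("xgboost")
  train <- generate_ranking_dataset(25, 15, separation = 1.5, seed = 31)
  test <- generate_ranking_dataset(25, 15, separation = 1.5, seed = 32)
  ours <- train_lambdamart(train, lambdamart_config(n_trees = 300))
  p <- predict_scores(ours, test)
  ndcg_ours <- mean(vapply(split(p$ranking$label, p$ranking$qid),
                           ndcg_at_k, numeric(1), k = 10))
  ord <- order(train$qid)
  dtrain <- xgboost::xgb.DMatrix(train$features[ord, ],
                                 label = train$label[ord],
                                 group = as.integer(table(train$qid[ord])))
  bst <- xgboost::xgb.train(
    params = list(objective = "rank:ndcg", eta = 0.1, max_depth = 4,
                  nthread = 1),
    data = dtrain, nrounds = 300, verbose = 0)
  sc <- predict(bst, xgboost::xgb.DMatrix(test$features))
  ndcg_xgb <- mean(vapply(
    split(seq_along(sc), test$qid), function(ix)
      ndcg_at_k(rank_labels(sc[ix], test$label[ix], test$did[ix]), k = 10),
    numeric(1)))
  expect_gte(ndcg_ours, ndcg_xgb - 0.05)
})
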