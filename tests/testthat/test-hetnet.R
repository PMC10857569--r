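test_that("edge lists are read, typed, deduplicated and validated", {
  dir <- withr::local_tempdir()
  paths <- write_edge_fixture(list(
    circ_cancer = data.frame(source_id = c("r1", "r2", "r1"),
                             target_id = c("c1", "c1", "c2")),
    drug_cancer = data.frame(source_id = "d1", target_id = "c1"),
    circ_drug = data.frame(source_id = c("r1", "r2"),
                           target_id = c("d1", "d1"))), dir)
  edges <- read_edge_lists(paths)
  expect_equal(nrow(edges), 6)
  expect_setequal(unique(edges$relation),
                  c("circ_cancer", "drug_cancer", "circ_drug"))
  expect_true(all(edges$source_type[edges$relation == "circ_drug"] ==
                    "circRNA"))

  # duplicate rows collapse with a warning
  dup <- write_edge_fixture(list(
    circ_cancer = data.frame(source_id = c("r1", "r1"),
                             target_id = c("c1", "c1"))), dir)
  expect_warning(e2 <- read_edge_lists(dup["circ_cancer"]), "duplicate")
  expect_equal(nrow(e2), 1)

  # identical source and target identifiers are rejected
  bad <- write_edge_fixture(list(
    circ_cancer = data.frame(source_id = "r1", target_id = "r1")), dir)
  expect_error(read_edge_lists(bad["circ_cancer"]), "coincide")

  # missing header column
  p <- file.path(dir, "nohdr.tsv")
  writeLines(c("a\tb", "r1\tc1"), p)
  expect_error(read_edge_lists(c(circ_cancer = p)), "source_id")
})

test_that("build_network keeps exactly the edge-incident nodes", {
  e <- data.frame(source_id = "r1", source_type = "circRNA",
                  target_id = "c1", target_type = "cancer",
                  relation = "circ_cancer", stringsAsFactors = FALSE)
  net <- build_network(e)
  expect_equal(nrow(net$nodes), 2)
  expect_equal(nrow(net$edges), 1)
  expect_false("r9" %in% net$nodes$id)  # never-referenced node absent
  expect_error(build_network(e[0, ]), "non-empty")

  # every node has degree >= 1 on a larger synthetic network
  sim <- generate_hetnet(synthetic_config(seed = 5))
  deg <- tabulate(c(sim$net$edges$source_idx, sim$net$edges$target_idx),
                  nbins = nrow(sim$net$nodes))
  expect_true(all(deg >= 1))
})

test_that("candidate pair enumeration covers the full Cartesian product", {
  net <- tiny_net()
  pairs <- enumerate_candidate_pairs(net, "circRNA")
  expect_equal(nrow(pairs), 4 * 3)
  expect_equal(sum(pairs$label), 4)
  expect_equal(sum(pairs$label == 0), 4 * 3 - 4)
  # positives are exactly the observed edges
  obs <- net$edges[net$edges$relation == "circ_cancer", ]
  expect_setequal(paste(pairs$query_id[pairs$label == 1],
                        pairs$cancer_id[pairs$label == 1]),
                  paste(obs$source_id, obs$target_id))

  one <- build_network(data.frame(
    source_id = "r1", source_type = "circRNA", target_id = "c1",
    target_type = "cancer", relation = "circ_cancer",
    stringsAsFactors = FALSE))
  p1 <- enumerate_candidate_pairs(one, "circRNA")
  expect_equal(sum(p1$label == 0), 0)
  expect_error(enumerate_candidate_pairs(net, "cancer"))
})

test_that("network_stats reports conserved counts, invariant to labels", {
  net <- tiny_net()
  st <- network_stats(net)
  expect_equal(st$n_nodes, sum(unlist(st$nodes_by_type)))
  expect_equal(st$n_edges, sum(unlist(st$edges_by_relation)))
  expect_equal(st$n_nodes, 9)
  expect_equal(st$n_edges, 8)

  # relabeling nodes leaves the summary unchanged
  e2 <- net$edges
  perm <- function(x) paste0("node_", x)
  e2$source_id <- perm(e2$source_id)
  e2$target_id <- perm(e2$target_id)
  st2 <- network_stats(build_network(e2[, 1:5]))
  expect_equal(st2$n_nodes, st$n_nodes)
  expect_equal(st2$nodes_by_type, st$nodes_by_type)
  expect_equal(st2$edges_by_relation, st$edges_by_relation)
  expect_equal(st2$degree, st$degree)
})

test_that("sensitivity edges follow the exact Wilcoxon + BH contract", {
  # two circRNAs whose median split yields groups {1,2,3} vs {4,5,6}
  # response: exact two-sided p = 0.1 -> no edge at alpha = 0.05
  expr <- rbind(rA = c(1, 1, 1, 2, 2, 2))
  colnames(expr) <- paste0("s", 1:6)
  resp <- rbind(dX = c(4, 5, 6, 1, 2, 3))
  colnames(resp) <- paste0("s", 1:6)
  out <- derive_sensitivity_edges(expr, resp, alpha = 0.05)
  tests <- attr(out, "tests")
  expect_equal(tests$p, 0.1, tolerance = 1e-12)
  expect_equal(nrow(out), 0)
  # m = 1 BH identity
  expect_equal(tests$q, tests$p)

  # identical response distributions -> p = 1, no edge
  resp_flat <- rbind(dX = c(7, 8, 9, 7, 8, 9))
  colnames(resp_flat) <- paste0("s", 1:6)
  out2 <- derive_sensitivity_edges(expr, resp_flat)
  expect_equal(attr(out2, "tests")$p, 1)
  expect_equal(nrow(out2), 0)

  # strongly separated response with 4v4 groups (exact two-sided
  # p = 2/70 < 0.05) -> edge emitted
  expr8 <- rbind(rA = c(1, 1, 1, 1, 2, 2, 2, 2))
  colnames(expr8) <- paste0("s", 1:8)
  resp_sep <- rbind(dX = c(101, 102, 103, 104, 1, 2, 3, 4))
  colnames(resp_sep) <- paste0("s", 1:8)
  out3 <- derive_sensitivity_edges(expr8, resp_sep)
  expect_equal(attr(out3, "tests")$p, 2 / 70, tolerance = 1e-12)
  expect_equal(nrow(out3), 1)
  expect_equal(out3$relation, "circ_drug")

  # degenerate grouping skipped with a warning
  expr_const <- rbind(rA = rep(1, 6))
  colnames(expr_const) <- paste0("s", 1:6)
  expect_warning(out4 <- derive_sensitivity_edges(expr_const, resp),
                 "fewer than 2")
  expect_equal(nrow(attr(out4, "tests")), 0)
})

test_that("wilcox.test matches exhaustive rank enumeration at small n", {
  set.seed(7)
  for (i in 1:10) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    vals <- sample(1000, n1 + n2)  # untied
    x <- vals[seq_len(n1)]
    y <- vals[-seq_len(n1)]
    p_pkg <- suppressWarnings(wilcox.test(x, y)$p.value)
    expect_equal(p_pkg, wilcox_exact_oracle(x, y), tolerance = 1e-10)
  }
})

test_that("canonical edge list round-trips through TSV", {
  net <- tiny_net()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net$edges, path)
  back <- read_edge_list(path)
  expect_equal(back, net$edges[, colnames(back)])
})
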