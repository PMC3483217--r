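test_that("interconnectivity counts members with internal edges", {
  ia <- ia_from_pairs("a", "b", "c", "d", "a", "e")
  r <- interconnectivity(ia, c("a", "b", "c"))
  expect_equal(r$n_present, 3)
  expect_equal(r$n_interconnected, 2)           # a and b share an edge; c does not
  expect_equal(r$fraction, 2 / 3)
  expect_setequal(r$interconnected, c("a", "b"))

  path <- ia_from_pairs("a", "b", "b", "c")
  expect_equal(interconnectivity(path, c("a", "c"))$fraction, 0)
  expect_equal(interconnectivity(ia_from_pairs("a", "b"), c("a", "b"))$fraction, 1)
  # absent members count in set_size but not the denominator
  r2 <- interconnectivity(path, c("a", "b", "zz"))
  expect_equal(r2$set_size, 3)
  expect_equal(r2$n_present, 2)
  expect_error(interconnectivity(path, c("x", "y")), "present")
})

test_that("permutation null is deterministic with add-one p-values", {
  set.seed(3)
  ia <- build_interactome(random_edge_df(40, 0.08))
  genes <- sample(nodes(ia), 8)
  a <- permutation_null(ia, genes, n_permutations = 99, seed = 5)
  b <- permutation_null(ia, genes, n_permutations = 99, seed = 5)
  expect_identical(a, b)
  expect_equal(a$p_value,
               (1 + sum(a$null_fractions >= a$observed)) / 100)
  expect_gt(a$p_value, 0)

  # on a complete graph every draw has fraction 1: p must be exactly 1
  kfull <- build_interactome(random_edge_df(8, 1))
  pk <- permutation_null(kfull, nodes(kfull)[1:4], n_permutations = 49, seed = 1)
  expect_equal(pk$p_value, 1)

  expect_error(permutation_null(ia, nodes(ia)[1], 99, 1), "at least 2")
})

test_that("a planted clique in a sparse graph is significant", {
  set.seed(9)
  edges <- random_edge_df(60, 0.03)
  clique_nodes <- paste0("n", 1:6)
  clq <- t(utils::combn(clique_nodes, 2))
  edges <- unique(rbind(edges, data.frame(gene_a = clq[, 1], gene_b = clq[, 2])))
  ia <- build_interactome(edges)
  p <- permutation_null(ia, clique_nodes, n_permutations = 999, seed = 2)
  expect_equal(p$observed, 1)
  expect_lt(p$p_value, 0.05)
  # degree-matched mode runs and is also deterministic
  d1 <- permutation_null(ia, clique_nodes, 99, seed = 4, sampling_mode = "degree_matched")
  d2 <- permutation_null(ia, clique_nodes, 99, seed = 4, sampling_mode = "degree_matched")
  expect_identical(d1, d2)
})

test_that("degree summaries use the simple graph and skip absent genes", {
  k3 <- ia_from_pairs("a", "b", "b", "c", "c", "a")
  expect_equal(degree_summary(k3)$mean, 2)
  star <- ia_from_pairs("h", "l1", "h", "l2", "h", "l3", "h", "l4")
  expect_equal(unname(degree_summary(star, "h")$degrees["h"]), 4)
  path <- ia_from_pairs("a", "b", "b", "c")
  s <- degree_summary(path, c("a", "c", "ghost"))
  expect_equal(s$mean, 1)
  expect_equal(s$n_absent, 1)
  expect_true(is.na(s$degrees["ghost"]))
})

test_that("hub connectivity counts genes touching one or all hubs", {
  ia <- ia_from_pairs("g1", "h1", "g2", "h1", "g2", "h2")
  h <- hub_connectivity(ia, c("g1", "g2", "g3"), c("h1", "h2"))
  expect_equal(h$n_any, 2)
  expect_equal(h$n_all, 1)
  expect_equal(h$genes_all, "g2")

  lonely <- hub_connectivity(ia, c("g1", "g3"), c("zz"))
  expect_equal(lonely$n_any, 0)
  expect_equal(lonely$n_all, 0)
  expect_error(hub_connectivity(ia, character(0), "h1"), "non-empty")
})

test_that("interconnectivity matches the pair-scan oracle on random graphs", {
  set.seed(21)
  for (i in 1:40) {
    edges <- random_edge_df(sample(5:10, 1), stats::runif(1, 0.15, 0.5))
    if (!nrow(edges)) next
    ia <- build_interactome(edges)
    genes <- sample(nodes(ia), sample(2:min(5, length(nodes(ia))), 1))
    got <- interconnectivity(ia, genes)
    want <- oracle_interconnectivity(edges, genes, nodes(ia))
    expect_equal(got$n_interconnected, want$n_interconnected)
    expect_equal(got$fraction, want$fraction)
  }
})
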