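toy_wln <- function(partners, core = "c1") {
  # minimal star network: core gene wired to every partner
  df <- data.frame(gene_a = core, gene_b = partners)
  build_longevity_network(build_interactome(df), gene_set(core, "worm"))
}

test_that("three selection criteria and provenance behave as specified", {
  wln <- toy_wln(c("w1", "w2"))
  cand <- select_candidates(wln,
                            gene_set(c("w2", "w3"), "worm"),
                            known_lags = gene_set("w3", "worm"),
                            essential = gene_set(c("w1", "w2", "w3"), "worm"))
  expect_setequal(cand$candidates$gene, c("w1", "w2"))
  expect_equal(cand$candidates$provenance[cand$candidates$gene == "w1"], "WLN_only")
  expect_equal(cand$candidates$provenance[cand$candidates$gene == "w2"], "shared")

  # essentiality annihilates everything
  none <- select_candidates(wln, gene_set(c("w2", "w3"), "worm"),
                            gene_set("zz", "worm"),
                            essential = gene_set(character(0), "worm"))
  expect_equal(nrow(none$candidates), 0)
  expect_true(all(none$filter_trail$excluded_by == "not_essential"))

  # known-LAG exclusion covers the whole pool
  known_all <- select_candidates(wln, gene_set("w3", "worm"),
                                 gene_set(c("w1", "w2", "w3"), "worm"),
                                 essential = gene_set(c("w1", "w2", "w3"), "worm"))
  expect_equal(nrow(known_all$candidates), 0)
  expect_true(all(known_all$filter_trail$excluded_by == "known_lag"))
})

test_that("filter trail accounts for every pool gene exactly once", {
  wln <- toy_wln(c("w1", "w2", "w4"))
  cand <- select_candidates(wln, gene_set(c("w2", "w3"), "worm"),
                            gene_set("w3", "worm"),
                            gene_set(c("w1", "w2"), "worm"))
  pool <- union(wln$partner_nodes, c("w2", "w3"))
  expect_setequal(cand$filter_trail$gene, pool)
  retained <- cand$filter_trail$gene[cand$filter_trail$excluded_by == ""]
  expect_setequal(retained, cand$candidates$gene)
  expect_equal(nrow(cand$filter_trail), length(pool))
})

test_that("clone availability filters preserve provenance and commute", {
  wln <- toy_wln(c("w1", "w2"))
  hln <- gene_set(c("w2", "w3"), "worm")
  known <- gene_set("w9", "worm")
  essential <- gene_set(c("w1", "w2", "w3"), "worm")
  clones <- gene_set(c("w2", "w3"), "worm")

  cand <- select_candidates(wln, hln, known, essential)
  a <- apply_clone_availability(cand, clones)
  expect_setequal(a$candidates$gene, c("w2", "w3"))
  expect_equal(a$candidates$provenance[a$candidates$gene == "w2"], "shared")

  # clone filter folded into the essentiality filter yields the same set:
  # the criteria are intersections, so order cannot matter
  ess_and_clones <- gene_set(intersect(essential$genes, clones$genes), "worm")
  b <- select_candidates(wln, hln, known, ess_and_clones)
  expect_setequal(a$candidates$gene, b$candidates$gene)

  # clones superset: identity
  all_clones <- apply_clone_availability(cand, gene_set(c("w1", "w2", "w3"), "worm"))
  expect_setequal(all_clones$candidates$gene, cand$candidates$gene)
})

test_that("partition counts always satisfy inclusion-exclusion", {
  wln <- toy_wln(paste0("w", 1:5))
  cand <- select_candidates(wln, gene_set(c("w4", "w5", "w6"), "worm"),
                            gene_set("none", "worm"),
                            gene_set(paste0("w", 1:6), "worm"))
  ct <- partition_counts(cand)
  expect_equal(ct$WLN_only + ct$HLN_only + ct$shared, ct$total)
  expect_equal(ct$WLN_only, 3)  # w1,w2,w3
  expect_equal(ct$shared, 2)    # w4,w5
  expect_equal(ct$HLN_only, 1)  # w6

  none <- apply_clone_availability(cand, gene_set("zz", "worm")) |>
    suppressMessages()
  expect_equal(partition_counts(none),
               list(WLN_only = 0L, HLN_only = 0L, shared = 0L, total = 0L))
})
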