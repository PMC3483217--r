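test_that("interactome generators are deterministic with model properties", {
  a <- gen_interactome(100, "erdos_renyi", p = 0.05, seed = 1)
  b <- gen_interactome(100, "erdos_renyi", p = 0.05, seed = 1)
  expect_identical(igraph::as_edgelist(a$graph), igraph::as_edgelist(b$graph))

  sf <- gen_interactome(200, "scale_free", m = 2, seed = 7)
  deg <- igraph::degree(sf$graph)
  expect_gt(max(deg), 3 * mean(deg))  # preferential attachment grows hubs

  cfgm <- gen_interactome(100, "configuration", seed = 3)
  expect_true(igraph::is_simple(cfgm$graph))

  expect_error(gen_interactome(5, "erdos_renyi"), ">= 10")
})

test_that("planted modules hit the target density and beat the null", {
  ia <- gen_interactome(200, "scale_free", m = 2, seed = 3)
  unchanged <- plant_core_module(ia, 20, density_boost = 1, seed = 3)
  expect_equal(igraph::ecount(unchanged$interactome$graph),
               igraph::ecount(ia$graph))

  planted <- plant_core_module(ia, 20, density_boost = 4, seed = 3)
  bg <- igraph::ecount(ia$graph) / choose(200, 2)
  internal <- igraph::ecount(igraph::induced_subgraph(
    planted$interactome$graph, planted$true_core))
  expect_gte(internal, ceiling(4 * bg * choose(20, 2)))

  p <- permutation_null(planted$interactome, planted$true_core,
                        n_permutations = 199, seed = 11)
  expect_lt(p$p_value, 0.05)

  expect_error(plant_core_module(ia, 200, 4, 1), "smaller")
  expect_error(plant_core_module(ia, 20, 1e6, 1), "exceeds 1")
})

test_that("essentiality labels respect fraction and core enrichment", {
  ia <- gen_interactome(600, "erdos_renyi", p = 0.02, seed = 5)
  expect_false(any(gen_annotations(ia, essential_fraction = 0, seed = 1)))
  expect_true(all(gen_annotations(ia, essential_fraction = 1, seed = 1)))

  core <- nodes(ia)[1:100]
  ess <- gen_annotations(ia, core = core, essential_fraction = 0.2,
                         core_essential_enrichment = 5, seed = 9)
  expect_equal(mean(ess[core]), 1)                       # 0.2 * 5 capped at 1
  expect_lt(abs(mean(ess[setdiff(names(ess), core)]) - 0.2), 0.05)
})

test_that("orthology generation covers and expands as configured", {
  genes <- sprintf("g%04d", 1:1000)
  bij <- gen_orthology(genes, coverage = 1, paralog_rate = 0, seed = 1)
  expect_equal(nrow(bij$pairs), 1000)
  expect_false(anyDuplicated(bij$pairs$gene_a) > 0)
  expect_false(anyDuplicated(bij$pairs$gene_b) > 0)

  none <- gen_orthology(genes, coverage = 0, seed = 1)
  expect_equal(nrow(none$pairs), 0)

  part <- gen_orthology(genes, coverage = 0.8, paralog_rate = 0, seed = 2)
  expect_lt(abs(length(unique(part$pairs$gene_a)) / 1000 - 0.8), 0.04)
})

test_that("lifespan samples follow the Gompertz law with AFT effects", {
  ls <- gen_lifespans(c(gA = 1), n_animals = 5000, censor_rate = 0, seed = 8)
  ks <- stats::ks.test(ls$control$times, function(q)
    flexsurv::pgompertz(q, shape = 0.25, rate = 0.00095))
  expect_gt(ks$p.value, 0.01)
  # control mean lifespan sits near the 20-day design point
  expect_lt(abs(mean(ls$control$times) - 20), 1)

  a <- gen_lifespans(c(g = 1.2), seed = 4)
  b <- gen_lifespans(c(g = 1.2), seed = 4)
  expect_identical(a$g$times, b$g$times)

  full_cens <- gen_lifespans(c(g = 1), censor_rate = 1, seed = 1)
  expect_error(km_estimate(full_cens$g), "censored")
  expect_error(gen_lifespans(c(g = 1), gompertz_shape = -1), "positive")
})

test_that("thrashing draws reflect true survival and degenerate cleanly", {
  # at very early days survival is ~1 for both arms: no phenotype
  th <- gen_thrashing(c(g = 1.5), days = c(0.1, 0.2, 0.3, 0.4), seed = 1)
  expect_equal(th$g$treated, rep(1, 4))
  expect_equal(classify_thrashing(th$g$treated, th$g$control)$phenotype, "none")

  # zero animals scored: the classifier's indeterminate path errors
  th0 <- gen_thrashing(c(g = 1.3), n_scored = 0, seed = 1)
  expect_error(classify_thrashing(th0$g$treated, th0$g$control), "indeterminate")
})

test_that("generated worlds are reproducible and re-load through readers", {
  cfg <- world_config(n_nodes = 150, core_size = 12, n_effect_genes = 3,
                      n_animals = 12)
  d1 <- tempfile("w1"); d2 <- tempfile("w2")
  w1 <- suppressMessages(gen_world(cfg, seed = 42, dir = d1))
  w2 <- suppressMessages(gen_world(cfg, seed = 42, dir = d2))
  for (f in names(w1$files)) {
    expect_identical(readLines(w1$files[[f]]), readLines(w2$files[[f]]),
                     info = f)
  }
  # every file round-trips through the package loaders
  recs <- read_edge_list(w1$files$edges)
  expect_identical(sort(nodes(build_interactome(recs))),
                   sort(nodes(w1$interactome)))
  expect_setequal(read_gene_set(w1$files$core, "worm")$genes, w1$true_core)
  expect_equal(nrow(read_orthology(w1$files$orthology)$pairs),
               nrow(w1$orthology$pairs))
  expect_true(w1$config$core_size < w1$config$n_nodes)

  expect_error(suppressMessages(
    gen_world(world_config(n_nodes = 50, core_size = 50), seed = 1)),
    "smaller")
})
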