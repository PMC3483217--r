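#' Generate a synthetic interactome
#'
#' Random simple undirected graphs emulating a protein-protein interaction
#' network: `"scale_free"` (Barabasi-Albert preferential attachment, heavy
#' tailed degrees like real interactomes), `"erdos_renyi"` (G(n, p)), or
#' `"configuration"` (fixed power-law degree sequence). Nodes are named
#' `g0001`, `g0002`, ...
#'
#' @param n_nodes number of genes (>= 10).
#' @param model `"scale_free"`, `"erdos_renyi"` or `"configuration"`.
#' @param m edges added per step (scale_free; default 2).
#' @param p edge probability (erdos_renyi; default 0.05).
#' @param gamma degree-distribution exponent (configuration; default 2.5).
#' @param seed integer seed; same seed gives an identical graph.
#' @return an `interactome`.
#' @export
gen_interactome <- function(n_nodes, model = c("scale_free", "erdos_renyi",
                                               "configuration"),
                            m = 2, p = 0.05, gamma = 2.5, seed = 1L) {
  model <- match.arg(model)
  if (!is_count(n_nodes) || n_nodes < 10)
    stop("n_nodes must be an integer >= 10")
  set.seed(as.integer(seed))
  g <- switch(model,
    scale_free = igraph::sample_pa(n_nodes, m = m, directed = FALSE),
    erdos_renyi = igraph::sample_gnp(n_nodes, p = p),
    configuration = {
      deg <- pmin(as.integer(round((stats::runif(n_nodes)^(-1 / (gamma - 1))))),
                  n_nodes - 1L)
      deg[deg < 1L] <- 1L
      if (sum(deg) %% 2 == 1) deg[which.max(deg)] <- deg[which.max(deg)] + 1L
      igraph::sample_degseq(deg, method = "vl")
    })
  g <- igraph::simplify(g)
  if (igraph::ecount(g) == 0) stop("model parameters yielded an empty graph")
  igraph::V(g)$name <- sprintf("g%04d", seq_len(n_nodes))
  structure(list(graph = g, species = "worm"), class = "interactome")
}

#' Plant a densely interconnected core module in an interactome
#'
#' Selects `k` nodes and adds random internal edges until the internal
#' pair-density reaches `density_boost` times the background edge density of
#' the input graph, emulating the elevated interconnectivity of
#' longevity-associated genes. `density_boost = 1` leaves the graph
#' unchanged (no boost).
#'
#' @param interactome an `interactome`.
#' @param k planted module size (`k < n_nodes`).
#' @param density_boost target internal density as a multiple of the
#'   background density (>= 1).
#' @param seed integer seed.
#' @return list with the augmented `interactome` and `true_core` (planted
#'   gene ids).
#' @export
plant_core_module <- function(interactome, k, density_boost = 4, seed = 1L) {
  stopifnot(inherits(interactome, "interactome"), is_count(k),
            density_boost >= 1)
  g <- interactome$graph
  n <- igraph::vcount(g)
  if (k >= n) stop("module size k must be smaller than the node count")
  set.seed(as.integer(seed))
  core <- sort(sample(igraph::V(g)$name, k))
  if (density_boost == 1)
    return(list(interactome = interactome, true_core = core))
  background <- igraph::ecount(g) / choose(n, 2)
  target_density <- density_boost * background
  if (target_density > 1)
    stop("requested internal density ", signif(target_density, 3), " exceeds 1")
  target_edges <- ceiling(target_density * choose(k, 2))
  sub <- igraph::induced_subgraph(g, core)
  have <- igraph::ecount(sub)
  if (have < target_edges) {
    all_pairs <- t(utils::combn(core, 2))
    el <- igraph::as_edgelist(sub)
    key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
    missing <- all_pairs[!(key(all_pairs) %in% if (nrow(el)) key(el) else character(0)), ,
                         drop = FALSE]
    add <- missing[sample.int(nrow(missing), target_edges - have), , drop = FALSE]
    g <- igraph::add_edges(g, t(add))
  }
  list(interactome = structure(list(graph = g, species = interactome$species),
                               class = "interactome"),
       true_core = core)
}

#' Generate boolean essentiality labels
#'
#' Background genes are essential with probability `essential_fraction`;
#' genes in `core` with probability `min(1, essential_fraction * enrichment)`,
#' mirroring the enrichment of longevity genes among essential genes.
#'
#' @param interactome an `interactome`.
#' @param core gene ids treated as the enriched class (may be empty).
#' @param essential_fraction background essentiality probability.
#' @param core_essential_enrichment enrichment factor for `core` genes.
#' @param seed integer seed.
#' @return named logical vector over all interactome genes.
#' @export
gen_annotations <- function(interactome, core = character(0),
                            essential_fraction = 0.35,
                            core_essential_enrichment = 2, seed = 1L) {
  stopifnot(inherits(interactome, "interactome"),
            essential_fraction >= 0, essential_fraction <= 1,
            core_essential_enrichment >= 0)
  ids <- nodes(interactome)
  set.seed(as.integer(seed))
  pr <- ifelse(ids %in% core,
               min(1, essential_fraction * core_essential_enrichment),
               essential_fraction)
  stats::setNames(stats::runif(length(ids)) < pr, ids)
}

#' Generate a many-to-many orthology map
#'
#' Each species-A gene is mapped with probability `coverage` to a mirrored
#' species-B id (`H_<gene>`); mapped genes gain an extra species-B paralog
#' (`H_<gene>_p2`) with probability `paralog_rate`.
#'
#' @param genes species-A gene ids.
#' @param coverage mapping probability in `[0, 1]`.
#' @param paralog_rate extra-paralog probability in `[0, 1]`.
#' @param species_pair labels `(species_a, species_b)`.
#' @param seed integer seed.
#' @return an [orthology_map()].
#' @export
gen_orthology <- function(genes, coverage = 0.7, paralog_rate = 0.1,
                          species_pair = c("worm", "human"), seed = 1L) {
  stopifnot(coverage >= 0, coverage <= 1, paralog_rate >= 0, paralog_rate <= 1)
  set.seed(as.integer(seed))
  mapped <- genes[stats::runif(length(genes)) < coverage]
  pairs <- data.frame(gene_a = character(0), gene_b = character(0),
                      cluster = character(0), stringsAsFactors = FALSE)
  if (length(mapped))
    pairs <- data.frame(gene_a = mapped, gene_b = paste0("H_", mapped),
                        cluster = paste0("c_", mapped), stringsAsFactors = FALSE)
  para <- mapped[stats::runif(length(mapped)) < paralog_rate]
  if (length(para))
    pairs <- rbind(pairs,
                   data.frame(gene_a = para, gene_b = paste0("H_", para, "_p2"),
                              cluster = paste0("c_", para),
                              stringsAsFactors = FALSE))
  orthology_map(pairs, species_pair = species_pair)
}

# internal: Gompertz survival probability at time t for an accelerated
# failure time factor f (death times are f * Gompertz(shape, rate)).
gompertz_survival <- function(t, shape, rate, factor = 1) {
  flexsurv::pgompertz(t / factor, shape = shape, rate = rate,
                      lower.tail = FALSE)
}

#' Generate Gompertz lifespan samples with per-gene effects
#'
#' Control death times follow a Gompertz mortality law; a gene with effect
#' `factor` multiplies every death time by `factor` (accelerated failure
#' time, which stays within the Gompertz family with shape and rate divided
#' by the factor). A fraction `censor_rate` of animals is right-censored at
#' a uniform time before death (bagging, rupture, wall deaths). Defaults give
#' a control mean lifespan near 20 days, the usual 20 degree assay window.
#'
#' @param gene_effects named numeric vector: gene id -> multiplicative
#'   lifespan factor (1 = no effect).
#' @param n_animals animals per group (>= 10).
#' @param gompertz_shape Gompertz shape (per day, > 0).
#' @param gompertz_rate Gompertz baseline hazard (per day, > 0).
#' @param censor_rate fraction of animals right-censored.
#' @param seed integer seed.
#' @return named list of [survival_dataset()]s, one per gene plus
#'   `"control"`.
#' @export
gen_lifespans <- function(gene_effects, n_animals = 90,
                          gompertz_shape = 0.25, gompertz_rate = 0.00095,
                          censor_rate = 0.05, seed = 1L) {
  stopifnot(is.numeric(gene_effects), !is.null(names(gene_effects)),
            is_count(n_animals), n_animals >= 10,
            censor_rate >= 0, censor_rate <= 1)
  if (gompertz_shape <= 0 || gompertz_rate <= 0)
    stop("Gompertz shape and rate must be positive")
  set.seed(as.integer(seed))
  draw_group <- function(factor, group) {
    t_death <- factor * flexsurv::rgompertz(n_animals, shape = gompertz_shape,
                                            rate = gompertz_rate)
    cens <- stats::runif(n_animals) < censor_rate
    times <- ifelse(cens, stats::runif(n_animals, 0, t_death), t_death)
    times <- pmax(times, 1e-6)
    survival_dataset(times, events = as.integer(!cens), group = group)
  }
  out <- lapply(names(gene_effects),
                function(g) draw_group(gene_effects[[g]], g))
  names(out) <- names(gene_effects)
  out$control <- draw_group(1, "control")
  out
}

#' Generate thrashing-assay survival fractions
#'
#' For each gene and scoring day, draws the number of animals alive among
#' `n_scored` as a binomial sample with success probability equal to the
#' group's true Gompertz survival at that day (with the gene's accelerated
#' failure time factor); matched control wells are drawn the same way with
#' factor 1.
#'
#' @param gene_effects named numeric vector of lifespan factors.
#' @param gompertz_shape,gompertz_rate control mortality law (see
#'   [gen_lifespans()]).
#' @param days scoring days of adulthood.
#' @param n_scored animals scored per well per day (>= 30 in practice).
#' @param seed integer seed.
#' @return named list per gene: list with `treated`, `control` (fractions per
#'   day), `n_scored`, `days`.
#' @export
gen_thrashing <- function(gene_effects, gompertz_shape = 0.25,
                          gompertz_rate = 0.00095, days = c(15, 17, 19, 21),
                          n_scored = 30, seed = 1L) {
  stopifnot(is.numeric(gene_effects), !is.null(names(gene_effects)),
            is_count(n_scored))
  set.seed(as.integer(seed))
  s_control <- gompertz_survival(days, gompertz_shape, gompertz_rate)
  out <- lapply(names(gene_effects), function(g) {
    s_treat <- gompertz_survival(days, gompertz_shape, gompertz_rate,
                                 factor = gene_effects[[g]])
    treated <- if (n_scored > 0)
      stats::rbinom(length(days), n_scored, s_treat) / n_scored else rep(0, length(days))
    control <- if (n_scored > 0)
      stats::rbinom(length(days), n_scored, s_control) / n_scored else rep(0, length(days))
    list(treated = treated, control = control, n_scored = n_scored,
         days = days)
  })
  names(out) <- names(gene_effects)
  out
}

#' Default synthetic-world configuration
#'
#' The fixed study conditions used by [gen_world()]: a 1000-gene scale-free
#' interactome with a planted 70-gene core at 4x internal density, 35%
#' background essentiality with 2-fold core enrichment, 70% orthology
#' coverage with 10% paralogy, 80% RNAi clone availability, 20 planted
#' effect genes with lifespan factors 1.3 (long) / 0.7 (short), 90 animals
#' per longitudinal group and 30 scored per thrashing well at days
#' 15/17/19/21.
#'
#' @param ... named overrides of individual fields.
#' @return a named list of generator parameters.
#' @export
world_config <- function(...) {
  cfg <- list(n_nodes = 1000, model = "scale_free", m = 2, p = 0.05,
              core_size = 70, density_boost = 4,
              essential_fraction = 0.35, core_essential_enrichment = 2,
              orthology_coverage = 0.7, paralog_rate = 0.1,
              clone_prob = 0.8, known_extra_frac = 0.05,
              n_effect_genes = 20, effect_long = 1.3, effect_short = 0.7,
              n_animals = 90, gompertz_shape = 0.25, gompertz_rate = 0.00095,
              censor_rate = 0.05, days = c(15, 17, 19, 21), n_scored = 30)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Generate a complete synthetic study world
#'
#' One call produces every input the pipeline consumes, with known ground
#' truth: an interactome with a planted core module, essentiality labels, an
#' orthology map to a mirrored second species, a human-side partner gene set,
#' a known-gene exclusion list, clone availability, and per-gene lifespan and
#' thrashing data for all realized candidates, of which `n_effect_genes` are
#' planted true effects (alternating long/short factors). With `dir` given,
#' all inputs are also written as plain-text files that re-load through the
#' package readers.
#'
#' @param config list from [world_config()].
#' @param seed master integer seed; child seeds are derived per component via
#'   [child_seed()], so regenerating one component never perturbs another.
#' @param dir optional output directory for the on-disk representation.
#' @return object of class `synthetic_world`; fields include `interactome`,
#'   `true_core`, `essential`, `orthology`, `hln_partners`, `known_lags`,
#'   `clones`, `candidates` (realized candidate ids), `effect_genes`,
#'   `lifespan_effects`, `lifespans`, `thrashing`, `config`, `seed`, and
#'   `files` (paths, when written).
#' @export
gen_world <- function(config = world_config(), seed = 42L, dir = NULL) {
  cfg <- config
  if (cfg$core_size >= cfg$n_nodes)
    stop("core_size must be smaller than n_nodes")
  ia <- gen_interactome(cfg$n_nodes, model = cfg$model, m = cfg$m, p = cfg$p,
                        seed = child_seed(seed, "interactome"))
  planted <- plant_core_module(ia, cfg$core_size, cfg$density_boost,
                               seed = child_seed(seed, "plant"))
  ia <- planted$interactome
  true_core <- planted$true_core
  essential <- gen_annotations(ia, core = true_core,
                               essential_fraction = cfg$essential_fraction,
                               core_essential_enrichment = cfg$core_essential_enrichment,
                               seed = child_seed(seed, "essential"))
  orth <- gen_orthology(nodes(ia), coverage = cfg$orthology_coverage,
                        paralog_rate = cfg$paralog_rate,
                        seed = child_seed(seed, "orthology"))
  core_set <- gene_set(true_core, species = "worm", label = "core LAGs")
  wln <- build_longevity_network(ia, core_set)
  partners <- wln$partner_nodes
  # the human-network partner pool: orthologs of half the worm partners plus
  # an equal number of random non-partner genes (emulates partners private to
  # the second species' network)
  set.seed(child_seed(seed, "hln"))
  half <- sample(partners, ceiling(length(partners) / 2))
  extra <- sample(setdiff(nodes(ia), union(partners, true_core)),
                  min(length(half), cfg$n_nodes - length(partners) - length(true_core)))
  hln_worm_side <- union(half, extra)
  hln_human <- orth$pairs$gene_b[orth$pairs$gene_a %in% hln_worm_side]
  hln_partners <- gene_set(hln_human, species = "human",
                           label = "HLN first-order partners")
  set.seed(child_seed(seed, "known"))
  known_extra <- sample(partners,
                        max(0, round(cfg$known_extra_frac * length(partners))))
  known_lags <- gene_set(union(true_core, known_extra), species = "worm",
                         label = "known LAGs")
  set.seed(child_seed(seed, "clones"))
  clone_ids <- nodes(ia)[stats::runif(cfg$n_nodes) < cfg$clone_prob]
  clones <- gene_set(clone_ids, species = "worm", label = "clone-available")
  # realized candidates, by the same criteria the prediction stage applies
  hln_back <- map_gene_set(hln_partners, orth, "ba")$mapped
  ess_set <- gene_set(names(essential)[essential], species = "worm",
                      label = "essential")
  cand <- select_candidates(wln, hln_back, known_lags, ess_set)
  cand <- apply_clone_availability(cand, clones)
  cand_ids <- cand$candidates$gene
  if (length(cand_ids) < cfg$n_effect_genes)
    stop("only ", length(cand_ids), " candidates realized; cannot plant ",
         cfg$n_effect_genes, " effect genes")
  set.seed(child_seed(seed, "effects"))
  effect_genes <- sort(sample(cand_ids, cfg$n_effect_genes))
  factors <- rep(c(cfg$effect_long, cfg$effect_short),
                 length.out = cfg$n_effect_genes)
  lifespan_effects <- stats::setNames(rep(1, length(cand_ids)), cand_ids)
  lifespan_effects[effect_genes] <- factors
  lifespans <- gen_lifespans(lifespan_effects, n_animals = cfg$n_animals,
                             gompertz_shape = cfg$gompertz_shape,
                             gompertz_rate = cfg$gompertz_rate,
                             censor_rate = cfg$censor_rate,
                             seed = child_seed(seed, "lifespans"))
  thrashing <- gen_thrashing(lifespan_effects,
                             gompertz_shape = cfg$gompertz_shape,
                             gompertz_rate = cfg$gompertz_rate,
                             days = cfg$days, n_scored = cfg$n_scored,
                             seed = child_seed(seed, "thrashing"))
  world <- structure(list(interactome = ia, true_core = true_core,
                          essential = essential, orthology = orth,
                          hln_partners = hln_partners, known_lags = known_lags,
                          clones = clones, candidates = cand,
                          effect_genes = effect_genes,
                          lifespan_effects = lifespan_effects,
                          lifespans = lifespans, thrashing = thrashing,
                          config = cfg, seed = as.integer(seed)),
                     class = "synthetic_world")
  if (!is.null(dir)) world$files <- write_world(world, dir)
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world> seed ", x$seed, ": ",
      igraph::vcount(x$interactome$graph), " genes, ",
      length(x$true_core), " planted core, ",
      nrow(x$candidates$candidates), " candidates (",
      length(x$effect_genes), " true effects)\n", sep = "")
  invisible(x)
}

# internal: serialize a synthetic world as the pipeline's on-disk inputs
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  el <- igraph::as_edgelist(world$interactome$graph)
  utils::write.table(data.frame(gene_a = el[, 1], gene_b = el[, 2]),
                     p("edges.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(world$true_core, p("core.tsv"))
  writeLines(names(world$essential)[world$essential], p("essential.tsv"))
  writeLines(world$clones$genes, p("clones.tsv"))
  writeLines(world$known_lags$genes, p("known_lags.tsv"))
  writeLines(world$hln_partners$genes, p("hln_partners.tsv"))
  utils::write.table(world$orthology$pairs, p("orthology.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ls_rows <- do.call(rbind, lapply(names(world$lifespans), function(g) {
    d <- world$lifespans[[g]]
    data.frame(gene = g, day = d$times, event = d$events,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(ls_rows, p("lifespans.csv"), sep = ",", quote = FALSE,
                     row.names = FALSE)
  th_rows <- do.call(rbind, lapply(names(world$thrashing), function(g) {
    r <- world$thrashing[[g]]
    data.frame(gene = g, day = r$days,
               treated_alive = as.integer(round(r$treated * r$n_scored)),
               treated_total = r$n_scored,
               control_alive = as.integer(round(r$control * r$n_scored)),
               control_total = r$n_scored, stringsAsFactors = FALSE)
  }))
  utils::write.table(th_rows, p("thrashing.csv"), sep = ",", quote = FALSE,
                     row.names = FALSE)
  truth <- list(seed = world$seed, true_core = world$true_core,
                effect_genes = world$effect_genes,
                lifespan_effects = as.list(world$lifespan_effects[world$effect_genes]))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  stats::setNames(as.list(p(c("edges.tsv", "core.tsv", "essential.tsv",
                              "clones.tsv", "known_lags.tsv", "hln_partners.tsv",
                              "orthology.tsv", "lifespans.csv", "thrashing.csv",
                              "truth.json"))),
                  c("edges", "core", "essential", "clones", "known_lags",
                    "hln_partners", "orthology", "lifespans", "thrashing",
                    "truth"))
}
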