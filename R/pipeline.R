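#' Pipeline configuration
#'
#' Gathers all file paths and analysis constants for the two workflows. The
#' defaults hold the screen's fixed thresholds: a 10% thrashing
#' survival-change threshold on at least 3 of the 4 scored days, a log-rank
#' significance level of 0.05, and a 10% cutoff for "modest" lifespan
#' effects.
#'
#' @param edges,core,orthology,hln_partners,essential,known_lags,clones
#'   input file paths for the prediction workflow (see [run_predict()]).
#' @param lifespans,thrashing input file paths for the screen workflow.
#' @param out_dir output directory.
#' @param n_permutations interconnectivity permutations (>= 1).
#' @param seed integer seed for the permutation null.
#' @param sampling_mode `"uniform"` or `"degree_matched"`.
#' @param threshold thrashing relative-change threshold in `(0, 1)`.
#' @param min_timepoints qualifying scored days (1-4).
#' @param alpha log-rank significance level in `(0, 1)`.
#' @param modest_cutoff percent cutoff for modest effects.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(edges = NULL, core = NULL, orthology = NULL,
                            hln_partners = NULL, essential = NULL,
                            known_lags = NULL, clones = NULL,
                            lifespans = NULL, thrashing = NULL,
                            out_dir = tempfile("longnet_"),
                            n_permutations = 1000, seed = 1L,
                            sampling_mode = "uniform",
                            threshold = 0.10, min_timepoints = 3,
                            alpha = 0.05, modest_cutoff = 10) {
  stopifnot(threshold > 0, threshold < 1, min_timepoints >= 1,
            min_timepoints <= 4, alpha > 0, alpha < 1,
            n_permutations >= 1, modest_cutoff > 0)
  structure(list(edges = edges, core = core, orthology = orthology,
                 hln_partners = hln_partners, essential = essential,
                 known_lags = known_lags, clones = clones,
                 lifespans = lifespans, thrashing = thrashing,
                 out_dir = out_dir,
                 n_permutations = n_permutations, seed = as.integer(seed),
                 sampling_mode = sampling_mode, threshold = threshold,
                 min_timepoints = min_timepoints, alpha = alpha,
                 modest_cutoff = modest_cutoff),
            class = "pipeline_config")
}

#' Configuration round-trip through YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path`; `read_config` a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

# internal: read the per-animal lifespan CSV (gene, day, event); the reserved
# gene id "control" carries the shared control group.
read_lifespans_csv <- function(path) {
  if (!file.exists(path)) stop("lifespan file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "day", "event")
  if (!all(need %in% names(df)))
    stop("lifespan file must have columns gene, day, event: ", path)
  if (!nrow(df)) stop("empty lifespan file: ", path)
  out <- lapply(split(df, df$gene),
                function(d) survival_dataset(d$day, d$event, group = d$gene[1]))
  out
}

# internal: read the thrashing CSV (gene, day, treated_alive, treated_total,
# control_alive, control_total) into per-gene records.
read_thrashing_csv <- function(path) {
  if (!file.exists(path)) stop("thrashing file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "day", "treated_alive", "treated_total",
            "control_alive", "control_total")
  if (!all(need %in% names(df)))
    stop("thrashing file must have columns ", paste(need, collapse = ", "),
         ": ", path)
  if (!nrow(df)) stop("empty thrashing file: ", path)
  lapply(split(df, df$gene), function(d) {
    d <- d[order(d$day), ]
    list(treated = d$treated_alive / d$treated_total,
         control = d$control_alive / d$control_total,
         n_scored = d$treated_total, days = d$day)
  })
}

#' Run the candidate-prediction workflow
#'
#' Loads the interactome edge list and core gene set, builds the worm
#' longevity network, computes core interconnectivity with its permutation
#' null, transfers the human-network partner set through the orthology map,
#' applies the three selection criteria and the clone filter, and writes
#' `network.graphml`, `node_roles.tsv`, `candidates.tsv` and `report.json`
#' under `config$out_dir`. Log lines on stderr give the filter funnel
#' (pool, minus known genes, essential, clone-available).
#'
#' @param config a [pipeline_config()] with the prediction inputs set.
#' @return the report, invisibly a list: network counts, coverage,
#'   interconnectivity + permutation p-value, partition counts, funnel,
#'   and a provenance block (config, seed).
#' @export
run_predict <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  records <- stage("load_edges", read_edge_list(config$edges))
  ia <- stage("build_interactome", build_interactome(records, species = "worm"))
  core <- stage("load_core", read_gene_set(config$core, species = "worm",
                                           label = "core LAGs"))
  wln <- stage("build_network", build_longevity_network(ia, core))
  cov <- coverage_fraction(wln, core, ia)
  ic <- stage("interconnectivity", interconnectivity(ia, core))
  pnull <- stage("permutation_null",
                 permutation_null(ia, core, n_permutations = config$n_permutations,
                                  seed = config$seed,
                                  sampling_mode = config$sampling_mode))
  orth <- stage("load_orthology",
                read_orthology(config$orthology, species_pair = c("worm", "human")))
  hln <- stage("load_hln_partners",
               read_gene_set(config$hln_partners, species = "human",
                             label = "HLN partners"))
  hln_back <- stage("map_orthologs", map_gene_set(hln, orth, "ba"))
  known <- stage("load_known", read_gene_set(config$known_lags, species = "worm",
                                             label = "known LAGs"))
  ess <- stage("load_essential", read_gene_set(config$essential, species = "worm",
                                               label = "essential"))
  clones <- stage("load_clones", read_gene_set(config$clones, species = "worm",
                                               label = "clone-available"))
  cand <- stage("select_candidates",
                select_candidates(wln, hln_back$mapped, known, ess))
  pool_n <- nrow(cand$filter_trail)
  after_known <- pool_n - sum(cand$filter_trail$excluded_by == "known_lag")
  after_ess <- after_known - sum(cand$filter_trail$excluded_by == "not_essential")
  cand <- stage("clone_filter", apply_clone_availability(cand, clones))
  after_clone <- cand$counts$total
  message("funnel: pool ", pool_n, " -> minus known LAGs ", after_known,
          " -> essential ", after_ess, " -> clone-available ", after_clone)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_network(wln, file.path(config$out_dir, "network.graphml"), "graphml")
  roles <- data.frame(gene = c(wln$core_nodes, wln$partner_nodes),
                      role = rep(c("core", "partner"),
                                 c(length(wln$core_nodes),
                                   length(wln$partner_nodes))))
  utils::write.table(roles, file.path(config$out_dir, "node_roles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cand_out <- merge(cand$candidates,
                    cand$filter_trail[, c("gene", "excluded_by")], by = "gene")
  names(cand_out)[names(cand_out) == "excluded_by"] <- "criteria"
  cand_out$criteria <- "all_passed"
  utils::write.table(cand_out[order(cand_out$gene), ],
                     file.path(config$out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(
    schema_version = "1.0",
    network = wln$counts,
    coverage_fraction = cov,
    interconnectivity = list(set_size = ic$set_size, n_present = ic$n_present,
                             n_interconnected = ic$n_interconnected,
                             fraction = ic$fraction),
    permutation = list(p_value = pnull$p_value,
                       null_mean = mean(pnull$null_fractions),
                       n_permutations = pnull$n_permutations,
                       sampling_mode = pnull$sampling_mode,
                       seed = pnull$seed),
    ortholog_transfer = list(n_input = hln_back$report$n_input,
                             n_mapped = hln_back$report$n_mapped,
                             n_unmapped = length(hln_back$report$unmapped)),
    funnel = list(pool = pool_n, after_known = after_known,
                  after_essential = after_ess, after_clones = after_clone),
    partition = cand$counts,
    provenance = list(seed = config$seed,
                      n_permutations = config$n_permutations,
                      sampling_mode = config$sampling_mode))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Run the screen-statistics workflow
#'
#' Classifies every gene's thrashing record into long/short/none, confirms
#' preliminary hits longitudinally by Kaplan-Meier/log-rank at
#' `config$alpha` (a hit is verified when the log-rank test is significant
#' and the direction of the mean-lifespan change agrees with the thrashing
#' call), computes per-gene lifespan effect measures, and writes
#' `effects.tsv` (verified genes) and `summary.json` (funnel counts,
#' verification frequencies, extrapolations, detection rates, effect
#' summaries) under `config$out_dir`.
#'
#' @param config a [pipeline_config()] with `lifespans` and `thrashing` set;
#'   optionally `candidates` provenance via a `candidates.tsv` in `out_dir`
#'   (written by [run_predict()]) for per-class detection rates.
#' @return the report list, invisibly.
#' @export
run_screen_stats <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  thr <- read_thrashing_csv(config$thrashing)
  ls_data <- read_lifespans_csv(config$lifespans)
  if (!"control" %in% names(ls_data))
    stop("lifespan file lacks the reserved 'control' group: ", config$lifespans)
  control <- ls_data$control
  genes <- setdiff(names(thr), "control")
  calls <- vapply(genes, function(g) {
    classify_thrashing(thr[[g]]$treated, thr[[g]]$control,
                       threshold = config$threshold,
                       min_timepoints = config$min_timepoints)$phenotype
  }, character(1))
  prelim_long <- genes[calls == "long"]
  prelim_short <- genes[calls == "short"]
  confirm <- function(g, want_sign) {
    if (!g %in% names(ls_data)) return(NULL)
    lt <- logrank_test(ls_data[[g]], control)
    pc <- percent_changes(ls_data[[g]], control)
    list(gene = g, p_value = lt$p_value,
         pct_delta_mean = pc$pct_delta_mean,
         pct_delta_max = pc$pct_delta_max,
         verified = lt$p_value < config$alpha &&
           sign(pc$pct_delta_mean) == want_sign)
  }
  res_long <- Filter(Negate(is.null), lapply(prelim_long, confirm, want_sign = 1))
  res_short <- Filter(Negate(is.null), lapply(prelim_short, confirm, want_sign = -1))
  verified_long <- Filter(function(r) r$verified, res_long)
  verified_short <- Filter(function(r) r$verified, res_short)
  summ <- screen_summary(
    genes_screened = length(genes),
    preliminary_long = length(prelim_long),
    preliminary_short = length(prelim_short),
    retested_long = length(res_long), retested_short = length(res_short),
    verified_long = length(verified_long),
    verified_short = length(verified_short))
  effects <- do.call(rbind, lapply(c(verified_long, verified_short), function(r)
    data.frame(gene = r$gene,
               pct_delta_mean = round_half_up(r$pct_delta_mean, 1),
               pct_delta_max = round_half_up(r$pct_delta_max, 1),
               p_value = r$p_value, stringsAsFactors = FALSE)))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(effects))
    effects <- data.frame(gene = character(0), pct_delta_mean = numeric(0),
                          pct_delta_max = numeric(0), p_value = numeric(0))
  utils::write.table(effects[order(-effects$pct_delta_mean), ],
                     file.path(config$out_dir, "effects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rates <- primary_detection_rates(length(genes), length(prelim_long),
                                   length(prelim_short))
  # per-provenance detection rates when a candidates.tsv is available
  by_class <- NULL
  cand_path <- file.path(config$out_dir, "candidates.tsv")
  if (file.exists(cand_path)) {
    cand <- utils::read.delim(cand_path, stringsAsFactors = FALSE)
    by_class <- lapply(split(cand$gene, cand$provenance), function(ids) {
      ids <- intersect(ids, genes)
      if (!length(ids)) return(NULL)
      primary_detection_rates(length(ids), sum(ids %in% prelim_long),
                              sum(ids %in% prelim_short))
    })
    by_class <- Filter(Negate(is.null), by_class)
  }
  safe_extrapolate <- function(prelim, retested, verified, screened) {
    if (retested == 0) return(list(count = 0, percent = 0))
    extrapolate_verified(prelim, retested, verified, screened)
  }
  ex_long <- safe_extrapolate(summ$preliminary_long, summ$retested_long,
                              summ$verified_long, summ$genes_screened)
  ex_short <- safe_extrapolate(summ$preliminary_short, summ$retested_short,
                               summ$verified_short, summ$genes_screened)
  eff_summary <- list()
  if (length(verified_long))
    eff_summary$long <- summarize_effects(
      effects[effects$pct_delta_mean > 0, , drop = FALSE], "long",
      modest_cutoff = config$modest_cutoff)
  if (length(verified_short))
    eff_summary$short <- summarize_effects(
      effects[effects$pct_delta_mean < 0, , drop = FALSE], "short",
      modest_cutoff = config$modest_cutoff)
  report <- list(
    schema_version = "1.0",
    summary = unclass(summ),
    verification_frequency = list(
      long = verification_frequency(summ, "long"),
      long_2dp = verification_frequency(summ, "long", digits = 2),
      short = verification_frequency(summ, "short"),
      short_2dp = verification_frequency(summ, "short", digits = 2)),
    extrapolation = list(long = ex_long, short = ex_short),
    detection_rates = c(list(all = rates), by_class),
    effect_summary = eff_summary,
    verified_genes = list(long = vapply(verified_long, `[[`, "", "gene"),
                          short = vapply(verified_short, `[[`, "", "gene")),
    provenance = list(alpha = config$alpha, threshold = config$threshold,
                      min_timepoints = config$min_timepoints,
                      modest_cutoff = config$modest_cutoff))
  jsonlite::write_json(report, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
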