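# internal: edge matrix of an interactome as a 2-column character matrix,
# cached on first use via an attribute-free local helper (cheap for the sizes
# handled here).
edge_matrix <- function(interactome) {
  igraph::as_edgelist(interactome$graph, names = TRUE)
}

#' Interconnectivity of a gene set within an interactome
#'
#' A member of the set counts as interconnected when it has at least one
#' interaction with a *different* member of the set. Members absent from the
#' interactome are excluded from the denominator but reported in `set_size`.
#'
#' @param interactome an `interactome`.
#' @param genes character vector (or [gene_set()]) of gene ids.
#' @return an object of class `interconnectivity_result`: list with
#'   `set_size`, `n_present`, `n_interconnected`, `fraction` and the
#'   interconnected gene ids (`interconnected`).
#' @examples
#' net <- build_interactome(data.frame(gene_a = c("a", "c", "a"),
#'                                     gene_b = c("b", "d", "e")))
#' interconnectivity(net, c("a", "b", "c"))$fraction  # 2/3
#' @export
interconnectivity <- function(interactome, genes) {
  stopifnot(inherits(interactome, "interactome"))
  if (inherits(genes, "gene_set")) genes <- genes$genes
  genes <- unique(genes)
  present <- intersect(genes, nodes(interactome))
  if (!length(present)) stop("no member of the gene set is present in the interactome")
  el <- edge_matrix(interactome)
  internal <- el[el[, 1] %in% present & el[, 2] %in% present, , drop = FALSE]
  inter <- unique(c(internal[, 1], internal[, 2]))
  structure(list(set_size = length(genes),
                 n_present = length(present),
                 n_interconnected = length(inter),
                 fraction = length(inter) / length(present),
                 interconnected = sort(inter)),
            class = "interconnectivity_result")
}

#' @export
print.interconnectivity_result <- function(x, ...) {
  cat("<interconnectivity> ", x$n_interconnected, "/", x$n_present,
      " present members interconnected (", sprintf("%.1f%%", 100 * x$fraction),
      "); set size ", x$set_size, "\n", sep = "")
  invisible(x)
}

# internal: interconnectivity fraction of a node index set, vectorized on a
# precomputed integer edge matrix (used by the permutation loop).
interconn_fraction_idx <- function(edge_idx, node_idx) {
  hit <- edge_idx[, 1] %in% node_idx & edge_idx[, 2] %in% node_idx
  if (!any(hit)) return(0)
  m <- edge_idx[hit, , drop = FALSE]
  length(unique(c(m[, 1], m[, 2]))) / length(node_idx)
}

#' Permutation null for gene-set interconnectivity
#'
#' Draws `n_permutations` random gene sets of the same size (same number of
#' interactome-present members as the observed set, since only those can
#' contribute edges) and computes the empirical probability of an
#' interconnectivity fraction at least as large as observed, with the add-one
#' correction \eqn{p = (1 + \#\{null \ge obs\}) / (1 + n)} so p is never 0.
#'
#' Sampling is uniform over interactome nodes by default ("randomized gene
#' sets of the same size"); `sampling_mode = "degree_matched"` samples within
#' 10 degree-quantile bins instead, which is the conservative choice for
#' high-degree sets.
#'
#' @param interactome an `interactome`.
#' @param genes gene ids or a [gene_set()]; at least 2 must be present.
#' @param n_permutations number of random sets (>= 1).
#' @param seed integer seed; identical seed gives identical output.
#' @param sampling_mode `"uniform"` or `"degree_matched"`.
#' @return object of class `permutation_null`: list with `observed`,
#'   `null_fractions`, `p_value`, `n_permutations`, `seed`, `sampling_mode`.
#' @export
permutation_null <- function(interactome, genes, n_permutations = 1000,
                             seed = 1L,
                             sampling_mode = c("uniform", "degree_matched")) {
  sampling_mode <- match.arg(sampling_mode)
  stopifnot(is_count(n_permutations), n_permutations >= 1)
  obs <- interconnectivity(interactome, genes)
  if (obs$n_present < 2)
    stop("need at least 2 interactome-present members to test interconnectivity")
  g <- interactome$graph
  all_nodes <- igraph::V(g)$name
  k <- obs$n_present
  if (k > length(all_nodes)) stop("gene-set size exceeds interactome node count")
  el <- igraph::as_edgelist(g, names = FALSE)
  present_idx <- match(intersect(unique(if (inherits(genes, "gene_set")) genes$genes else genes),
                                 all_nodes), all_nodes)
  if (sampling_mode == "degree_matched") {
    deg <- igraph::degree(g)
    brk <- unique(stats::quantile(deg, probs = seq(0, 1, length.out = 11)))
    bin <- cut(deg, breaks = brk, include.lowest = TRUE, labels = FALSE)
    target_bins <- bin[present_idx]
    bin_members <- split(seq_along(all_nodes), bin)
    bin_need <- table(target_bins)
  }
  null_fractions <- numeric(n_permutations)
  set.seed(as.integer(seed))
  for (i in seq_len(n_permutations)) {
    if (sampling_mode == "uniform") {
      draw <- sample.int(length(all_nodes), k)
    } else {
      draw <- unlist(lapply(names(bin_need), function(b) {
        pool <- bin_members[[b]]
        sample(pool, min(bin_need[[b]], length(pool)))
      }), use.names = FALSE)
      if (length(draw) < k)
        draw <- union(draw, sample(setdiff(seq_along(all_nodes), draw),
                                   k - length(draw)))
    }
    null_fractions[i] <- interconn_fraction_idx(el, draw)
  }
  p <- (1 + sum(null_fractions >= obs$fraction)) / (1 + n_permutations)
  structure(list(observed = obs$fraction,
                 n_present = obs$n_present,
                 null_fractions = null_fractions,
                 p_value = p,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 sampling_mode = sampling_mode),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("<permutation_null> observed ", sprintf("%.3f", x$observed),
      " vs null mean ", sprintf("%.3f", mean(x$null_fractions)),
      " (", x$n_permutations, " ", x$sampling_mode, " draws): p = ",
      format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Degree summary for an interactome or a gene set within it
#'
#' Degrees are computed on the simple graph. With `genes` given, members
#' absent from the interactome are reported with `NA` degree and excluded
#' from the summary statistics.
#'
#' @param interactome an `interactome`.
#' @param genes optional gene ids; default summarizes the whole interactome.
#' @return list with `degrees` (named vector, `NA` for absent genes),
#'   `mean`, `median`, `max`, `n_present`, `n_absent`.
#' @export
degree_summary <- function(interactome, genes = NULL) {
  stopifnot(inherits(interactome, "interactome"))
  deg_all <- igraph::degree(interactome$graph)
  if (is.null(genes)) {
    deg <- deg_all
    absent <- character(0)
  } else {
    if (inherits(genes, "gene_set")) genes <- genes$genes
    genes <- unique(genes)
    deg <- stats::setNames(deg_all[genes], genes)
    absent <- genes[!genes %in% names(deg_all)]
  }
  ok <- deg[!is.na(deg)]
  list(degrees = deg,
       mean = if (length(ok)) mean(ok) else NA_real_,
       median = if (length(ok)) stats::median(ok) else NA_real_,
       max = if (length(ok)) max(ok) else NA_real_,
       n_present = length(ok), n_absent = length(absent))
}

#' Connectivity of a gene set to designated hub genes
#'
#' For each gene, reports adjacency to each hub in the interactome, plus how
#' many genes touch at least one hub and how many touch all hubs (the
#' "connected to daf-2 / bar-1 / clk-2"-style summary). Genes absent from the
#' interactome count as connected to none.
#'
#' @param interactome an `interactome`.
#' @param genes non-empty gene ids to profile.
#' @param hubs non-empty hub gene ids.
#' @return list with `table` (logical gene x hub data.frame),
#'   `n_any` (genes adjacent to >= 1 hub), `n_all` (adjacent to every hub),
#'   and `genes_all` (ids adjacent to every hub).
#' @export
hub_connectivity <- function(interactome, genes, hubs) {
  stopifnot(inherits(interactome, "interactome"))
  if (inherits(genes, "gene_set")) genes <- genes$genes
  if (inherits(hubs, "gene_set")) hubs <- hubs$genes
  genes <- unique(genes); hubs <- unique(hubs)
  if (!length(hubs)) stop("hubs must be non-empty")
  if (!length(genes)) stop("genes must be non-empty")
  el <- edge_matrix(interactome)
  adj <- sapply(hubs, function(h) {
    nb <- c(el[el[, 1] == h, 2], el[el[, 2] == h, 1])
    genes %in% nb
  })
  adj <- matrix(adj, nrow = length(genes), ncol = length(hubs),
                dimnames = list(genes, hubs))
  n_hits <- rowSums(adj)
  list(table = as.data.frame(adj),
       n_any = sum(n_hits >= 1),
       n_all = sum(n_hits == length(hubs)),
       genes_all = genes[n_hits == length(hubs)])
}
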