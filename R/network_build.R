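#' Build an interactome from edge records
#'
#' Assembles a simple undirected graph from a parsed edge list: self-loops are
#' removed (with a reported count) and duplicate/reversed edges are collapsed.
#' The node set is the union of endpoints of the surviving edges.
#'
#' @param records data.frame from [read_edge_list()], or any data.frame with
#'   character columns `gene_a`, `gene_b`.
#' @param species species label for the interactome.
#' @return an object of class `interactome`: a list with an igraph `graph`
#'   and the `species` label. `attr(, "self_loops")` counts removed loops.
#' @examples
#' recs <- data.frame(gene_a = c("a", "b", "a"), gene_b = c("b", "a", "a"))
#' net <- build_interactome(recs)
#' igraph::ecount(net$graph)  # 1
#' @export
build_interactome <- function(records, species = "") {
  stopifnot(is.data.frame(records), all(c("gene_a", "gene_b") %in% names(records)),
            nrow(records) >= 1)
  loops <- records$gene_a == records$gene_b
  n_loops <- sum(loops)
  if (n_loops > 0)
    message("build_interactome: removed ", n_loops, " self-loop(s)")
  records <- records[!loops, , drop = FALSE]
  if (!nrow(records)) stop("empty graph: all records are self-loops")
  g <- igraph::graph_from_data_frame(records[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  out <- structure(list(graph = g, species = species), class = "interactome")
  attr(out, "self_loops") <- n_loops
  out
}

#' @export
print.interactome <- function(x, ...) {
  cat("<interactome> ", if (nzchar(x$species)) paste0(x$species, ": "),
      igraph::vcount(x$graph), " genes, ", igraph::ecount(x$graph),
      " interactions\n", sep = "")
  invisible(x)
}

#' @export
nodes <- function(x) UseMethod("nodes")

#' Gene ids present in a network object
#' @param x an `interactome` or `longevity_network`.
#' @return character vector of node names.
#' @export
nodes.interactome <- function(x) igraph::V(x$graph)$name

#' @export
nodes.longevity_network <- function(x) igraph::V(x$graph)$name

# internal constructor shared by build and GraphML re-load
new_longevity_network <- function(graph, core_nodes, partner_nodes, parent) {
  stopifnot(length(intersect(core_nodes, partner_nodes)) == 0)
  structure(list(graph = graph,
                 core_nodes = sort(core_nodes),
                 partner_nodes = sort(partner_nodes),
                 parent = parent),
            class = "longevity_network")
}

#' Construct a longevity network from a core gene set
#'
#' Three-step construction: (1) keep the core genes that have reported
#' interactions, i.e. core genes present in the interactome; (2) add all their
#' first-order interaction partners; (3) take the largest interconnected
#' subgraph — the largest connected component, by node count, of the subgraph
#' induced on the candidate node set. Ties on node count are broken by larger
#' core-gene count, then by the lexicographically smallest sorted node list,
#' so the result is deterministic. Partner-partner edges inside the candidate
#' set are retained (induced-subgraph semantics).
#'
#' @param interactome an [build_interactome()] object.
#' @param core a [gene_set()] of core longevity-associated genes.
#' @return an object of class `longevity_network` with elements `graph`
#'   (igraph), `core_nodes`, `partner_nodes`, `parent` (the interactome), and
#'   a `counts` list (core retained, partners, total).
#' @export
build_longevity_network <- function(interactome, core) {
  stopifnot(inherits(interactome, "interactome"), inherits(core, "gene_set"))
  if (!length(core$genes)) stop("core gene set is empty")
  g <- interactome$graph
  core_in <- intersect(core$genes, igraph::V(g)$name)
  if (!length(core_in)) stop("no core gene has interactions in the interactome")
  nbr_idx <- unique(unlist(igraph::adjacent_vertices(g, core_in)))
  nbrs <- igraph::V(g)$name[nbr_idx]
  candidates <- union(core_in, nbrs)
  sub <- igraph::induced_subgraph(g, candidates)
  comp <- igraph::components(sub)
  members <- split(igraph::V(sub)$name, comp$membership)
  sizes <- lengths(members)
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    core_counts <- vapply(members[best],
                          function(m) length(intersect(m, core_in)), integer(1))
    best <- best[core_counts == max(core_counts)]
    if (length(best) > 1) {
      keys <- vapply(members[best],
                     function(m) paste(sort(m), collapse = "\r"), character(1))
      best <- best[order(keys)][1L]
    }
  }
  keep <- members[[best[1L]]]
  net_g <- igraph::induced_subgraph(sub, keep)
  core_nodes <- intersect(keep, core_in)
  partner_nodes <- setdiff(keep, core_in)
  # every partner must touch at least one core gene, by construction
  if (length(partner_nodes)) {
    has_core_nbr <- vapply(partner_nodes, function(p) {
      nb <- igraph::V(g)$name[unlist(igraph::adjacent_vertices(g, p))]
      length(intersect(nb, core_nodes)) > 0
    }, logical(1))
    stopifnot(all(has_core_nbr))
  }
  out <- new_longevity_network(net_g, core_nodes, partner_nodes,
                               parent = interactome)
  out$counts <- list(core_retained = length(core_nodes),
                     partners = length(partner_nodes),
                     total = length(keep))
  out
}

#' @export
print.longevity_network <- function(x, ...) {
  cat("<longevity_network> ", length(x$core_nodes), " core + ",
      length(x$partner_nodes), " partner genes, ",
      igraph::ecount(x$graph), " edges\n", sep = "")
  invisible(x)
}

#' Fraction of interactome-present core genes retained in the network
#'
#' The share of core genes with reported interactions that end up in the
#' (connected) longevity network — e.g. 205 of 218 gives 0.94, reported as
#' "94%" coverage.
#'
#' @param network a `longevity_network` built from `core` and `interactome`.
#' @param core the core [gene_set()].
#' @param interactome the source `interactome`.
#' @return a fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(network, core, interactome) {
  stopifnot(inherits(network, "longevity_network"),
            inherits(core, "gene_set"), inherits(interactome, "interactome"))
  denom <- length(intersect(core$genes, nodes(interactome)))
  if (denom == 0) stop("no core gene is present in the interactome")
  length(network$core_nodes) / denom
}
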