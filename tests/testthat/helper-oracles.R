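# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (pair scans, subset enumeration, explicit risk tables)
# so they cannot share a defect with the implementation they check.

# build an interactome from a flat vector of endpoint pairs: ep("a","b","b","c")
ia_from_pairs <- function(...) {
  v <- c(...)
  build_interactome(data.frame(gene_a = v[c(TRUE, FALSE)],
                               gene_b = v[c(FALSE, TRUE)],
                               stringsAsFactors = FALSE))
}

# random simple graph as an edge data.frame over nodes n1..n_nodes
random_edge_df <- function(n_nodes, p_edge) {
  ids <- paste0("n", seq_len(n_nodes))
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  data.frame(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
             stringsAsFactors = FALSE)
}

# O(|S|^2) pair-scan interconnectivity oracle on a raw edge data.frame
oracle_interconnectivity <- function(edges, genes, node_ids) {
  present <- intersect(genes, node_ids)
  has_edge <- function(x, y) {
    any((edges$gene_a == x & edges$gene_b == y) |
        (edges$gene_a == y & edges$gene_b == x))
  }
  inter <- vapply(present, function(g) {
    any(vapply(setdiff(present, g), function(h) has_edge(g, h), logical(1)))
  }, logical(1))
  list(n_present = length(present), n_interconnected = sum(inter),
       fraction = if (length(present)) sum(inter) / length(present) else NaN)
}

# connectivity of a node subset under an adjacency matrix, by naive frontier
# expansion (no igraph)
subset_connected <- function(adj, members) {
  if (length(members) <= 1) return(TRUE)
  reached <- members[1]
  repeat {
    nxt <- unique(c(reached, members[colSums(adj[reached, members, drop = FALSE]) > 0]))
    if (length(nxt) == length(reached)) break
    reached <- nxt
  }
  length(reached) == length(members)
}

# brute-force "largest interconnected sub-graph": enumerate every subset of
# the candidate nodes, keep connected induced subgraphs, maximize node count
# with the tie-break (core count, then lexicographically smallest node list)
oracle_largest_subgraph <- function(edges, candidates, core) {
  stopifnot(length(candidates) <= 14)
  ids <- sort(candidates)
  k <- length(ids)
  adj <- matrix(FALSE, k, k, dimnames = list(ids, ids))
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    if (a %in% ids && b %in% ids && a != b) adj[a, b] <- adj[b, a] <- TRUE
  }
  best <- NULL
  for (mask in seq_len(2^k) - 1L) {
    members <- ids[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
    if (!length(members)) next
    if (!subset_connected(adj, members)) next
    if (is.null(best)) { best <- members; next }
    if (length(members) > length(best)) { best <- members; next }
    if (length(members) == length(best)) {
      c_new <- length(intersect(members, core))
      c_old <- length(intersect(best, core))
      if (c_new > c_old ||
          (c_new == c_old &&
           paste(sort(members), collapse = " ") <
             paste(sort(best), collapse = " "))) best <- members
    }
  }
  sort(best)
}

# hand log-rank: observed-minus-expected over pooled risk sets, 1 df
oracle_logrank <- function(t1, e1, t2, e2) {
  times <- c(t1, t2); events <- c(e1, e2)
  grp1 <- c(rep(TRUE, length(t1)), rep(FALSE, length(t2)))
  dt <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (t in dt) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & grp1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & grp1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (O1 - E1)^2 / V
  list(statistic = stat,
       p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}
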