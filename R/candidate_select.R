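#' Select candidate longevity genes from worm and human longevity networks
#'
#' Applies the three selection criteria: a candidate must (1) be a first-order
#' partner in the worm longevity network or the worm ortholog of a human
#' longevity-network partner; (2) not be a previously reported
#' longevity-associated gene in any supplied species (lists mapped to worm
#' ids); (3) be essential for development and growth. Each pool gene's fate is
#' recorded in a filter trail, so pool genes appear exactly once either among
#' the candidates or in the exclusion trail.
#'
#' @param wln a `longevity_network` in the worm species (its
#'   `partner_nodes` are the WLN source pool).
#' @param hln_partner_orthologs [gene_set()] of worm orthologs of human
#'   longevity-network partners (the HLN source pool).
#' @param known_lags [gene_set()] of previously reported longevity genes
#'   (union over species, in worm ids).
#' @param essential [gene_set()] of genes essential for development/growth.
#' @return an object of class `candidate_set`: list with `candidates`
#'   data.frame (`gene`, `provenance` in {WLN_only, HLN_only, shared}),
#'   `filter_trail` data.frame (`gene`, `provenance`, `excluded_by` with ""
#'   for retained genes), and `counts` from [partition_counts()].
#' @export
select_candidates <- function(wln, hln_partner_orthologs, known_lags,
                              essential) {
  stopifnot(inherits(wln, "longevity_network"),
            inherits(hln_partner_orthologs, "gene_set"),
            inherits(known_lags, "gene_set"), inherits(essential, "gene_set"))
  wln_pool <- wln$partner_nodes
  hln_pool <- hln_partner_orthologs$genes
  pool <- union(wln_pool, hln_pool)
  if (!length(pool)) stop("empty candidate pool: no WLN partners and no HLN orthologs")
  provenance <- ifelse(pool %in% wln_pool & pool %in% hln_pool, "shared",
                       ifelse(pool %in% wln_pool, "WLN_only", "HLN_only"))
  excluded_by <- rep("", length(pool))
  excluded_by[pool %in% known_lags$genes] <- "known_lag"
  not_essential <- !(pool %in% essential$genes) & excluded_by == ""
  excluded_by[not_essential] <- "not_essential"
  trail <- data.frame(gene = pool, provenance = provenance,
                      excluded_by = excluded_by, stringsAsFactors = FALSE)
  trail <- trail[order(trail$gene), ]
  rownames(trail) <- NULL
  keep <- trail[trail$excluded_by == "", c("gene", "provenance")]
  rownames(keep) <- NULL
  new_candidate_set(keep, trail)
}

new_candidate_set <- function(candidates, filter_trail) {
  stopifnot(is.data.frame(candidates),
            all(c("gene", "provenance") %in% names(candidates)),
            !anyDuplicated(candidates$gene),
            all(candidates$provenance %in% c("WLN_only", "HLN_only", "shared")))
  out <- structure(list(candidates = candidates, filter_trail = filter_trail),
                   class = "candidate_set")
  out$counts <- partition_counts(out)
  out
}

#' @export
print.candidate_set <- function(x, ...) {
  ct <- x$counts
  cat("<candidate_set> ", ct$total, " candidates (WLN-only ", ct$WLN_only,
      ", HLN-only ", ct$HLN_only, ", shared ", ct$shared, ")\n", sep = "")
  invisible(x)
}

#' Restrict candidates to those with an available RNAi clone
#'
#' Intersects the candidate set with a clone-availability gene set;
#' provenance labels are preserved and counts recomputed. An empty result is
#' allowed (and messaged), since clone coverage is an external constraint,
#' not a selection criterion.
#'
#' @param candidates a `candidate_set`.
#' @param clones [gene_set()] of genes with available RNAi clones.
#' @return a filtered `candidate_set`; dropped genes gain
#'   `excluded_by = "no_clone"` in the trail.
#' @export
apply_clone_availability <- function(candidates, clones) {
  stopifnot(inherits(candidates, "candidate_set"), inherits(clones, "gene_set"))
  cand <- candidates$candidates
  keep <- cand$gene %in% clones$genes
  if (!any(keep)) message("apply_clone_availability: no candidate has a clone")
  trail <- candidates$filter_trail
  dropped <- cand$gene[!keep]
  trail$excluded_by[trail$gene %in% dropped & trail$excluded_by == ""] <- "no_clone"
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  new_candidate_set(out, trail)
}

#' Candidate counts per provenance class
#'
#' @param candidates a `candidate_set`.
#' @return list `(WLN_only, HLN_only, shared, total)`; the three classes
#'   always sum to `total`.
#' @export
partition_counts <- function(candidates) {
  stopifnot(inherits(candidates, "candidate_set"))
  p <- candidates$candidates$provenance
  out <- list(WLN_only = sum(p == "WLN_only"),
              HLN_only = sum(p == "HLN_only"),
              shared = sum(p == "shared"),
              total = length(p))
  stopifnot(out$WLN_only + out$HLN_only + out$shared == out$total)
  out
}
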