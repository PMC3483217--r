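#' Map a gene set across species through an orthology map
#'
#' Returns the non-redundant union of all orthologs of the input genes. The
#' mapping may be many-to-many: collisions are deduplicated, one-to-many
#' expansions and unmapped genes are enumerated in the mapping report so
#' transfer losses stay auditable.
#'
#' @param genes a [gene_set()] whose `species` matches the source side of
#'   `map`.
#' @param map an [orthology_map()].
#' @param direction `"ab"` (map species A ids to species B) or `"ba"`.
#' @return list with `mapped` (a [gene_set()] in the target species) and
#'   `report`: list(`n_input`, `n_mapped`, `unmapped` ids, `expansions`
#'   data.frame of genes with more than one ortholog).
#' @examples
#' om <- orthology_map(data.frame(gene_a = c("h1", "h1"), gene_b = c("w1", "w2")),
#'                     species_pair = c("human", "worm"))
#' map_gene_set(gene_set("h1", "human"), om, "ab")$mapped$genes
#' @export
map_gene_set <- function(genes, map, direction = c("ab", "ba")) {
  stopifnot(inherits(genes, "gene_set"), inherits(map, "orthology_map"))
  direction <- match.arg(direction)
  src_sp <- if (direction == "ab") map$species_pair[1] else map$species_pair[2]
  dst_sp <- if (direction == "ab") map$species_pair[2] else map$species_pair[1]
  if (genes$species != src_sp)
    stop("species mismatch: gene set is '", genes$species,
         "' but the ", direction, " source side of the map is '", src_sp, "'")
  pairs <- map$pairs
  if (direction == "ba")
    pairs <- data.frame(gene_a = pairs$gene_b, gene_b = pairs$gene_a,
                        stringsAsFactors = FALSE)
  hit <- pairs[pairs$gene_a %in% genes$genes, , drop = FALSE]
  per_gene <- split(hit$gene_b, hit$gene_a)
  per_gene <- lapply(per_gene, unique)
  mapped_ids <- sort(unique(as.character(unlist(per_gene, use.names = FALSE))))
  unmapped <- sort(setdiff(genes$genes, names(per_gene)))
  expn <- per_gene[lengths(per_gene) > 1]
  expansions <- data.frame(
    gene = names(expn),
    n_orthologs = lengths(expn),
    orthologs = vapply(expn, paste, character(1), collapse = ","),
    row.names = NULL, stringsAsFactors = FALSE)
  list(mapped = gene_set(mapped_ids, species = dst_sp,
                         label = paste0("orthologs of: ", genes$label)),
       report = list(n_input = length(genes$genes),
                     n_mapped = length(genes$genes) - length(unmapped),
                     unmapped = unmapped,
                     expansions = expansions))
}

#' Build a cross-species core gene set
#'
#' The core set for a native-species longevity network is the union of the
#' native longevity-associated genes and the non-redundant orthologs of
#' longevity-associated genes from other model organisms, each transferred
#' through its own orthology map. "Non-redundant" is a plain set union by
#' canonical id; all members of many-to-many ortholog clusters are kept.
#' Per-gene provenance records which species contributed each gene.
#'
#' @param native_lags a [gene_set()] in the native species.
#' @param foreign_lag_sets list of [gene_set()]s from other species.
#' @param maps list of [orthology_map()]s, one per foreign set, each mapping
#'   between the foreign species and the native species (either orientation).
#' @return list with `core` (a [gene_set()] in the native species),
#'   `provenance` (named list: gene -> character vector of contributing
#'   species, `"native"` first), and per-species mapping `reports`.
#' @export
build_cross_species_core <- function(native_lags, foreign_lag_sets = list(),
                                     maps = list()) {
  stopifnot(inherits(native_lags, "gene_set"),
            is.list(foreign_lag_sets), is.list(maps))
  if (length(foreign_lag_sets) != length(maps))
    stop("each foreign gene set needs exactly one orthology map (got ",
         length(foreign_lag_sets), " sets, ", length(maps), " maps)")
  prov <- stats::setNames(
    rep(list("native"), length(native_lags$genes)), native_lags$genes)
  reports <- list()
  for (i in seq_along(foreign_lag_sets)) {
    fs <- foreign_lag_sets[[i]]
    m <- maps[[i]]
    stopifnot(inherits(fs, "gene_set"), inherits(m, "orthology_map"))
    dir <- if (fs$species == m$species_pair[1] &&
               native_lags$species == m$species_pair[2]) "ab"
           else if (fs$species == m$species_pair[2] &&
                    native_lags$species == m$species_pair[1]) "ba"
           else stop("foreign set '", fs$species,
                     "' has no orthology map to native species '",
                     native_lags$species, "'")
    res <- map_gene_set(fs, m, dir)
    reports[[fs$species]] <- res$report
    for (gid in res$mapped$genes)
      prov[[gid]] <- unique(c(prov[[gid]], fs$species))
  }
  list(core = gene_set(names(prov), species = native_lags$species,
                       label = "cross-species core LAGs"),
       provenance = prov,
       reports = reports)
}
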