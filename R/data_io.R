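#' Gene alias maps
#'
#' An alias map translates mixed gene nomenclature (sequence names such as
#' "F37C12.9", common names such as "rps-14", database ids) to one canonical
#' id per gene. It is a plain named character vector: names are aliases,
#' values are canonical ids. Canonical ids always map to themselves, so
#' applying a map twice equals applying it once.
#'
#' @param aliases named character vector, names = alias, value = canonical id.
#' @return a validated alias map (named character vector).
#' @examples
#' am <- alias_map(c("rps-14" = "F37C12.9"))
#' canonicalize(c("rps-14", "F37C12.9", "unc-1"), am)
#' @export
alias_map <- function(aliases) {
  stopifnot(is.character(aliases), !is.null(names(aliases)))
  if (anyDuplicated(names(aliases)))
    stop("alias map is not a function: duplicated aliases: ",
         paste(unique(names(aliases)[duplicated(names(aliases))]), collapse = ", "))
  # canonical ids map to themselves
  canon <- setdiff(unname(aliases), names(aliases))
  out <- c(aliases, stats::setNames(canon, canon))
  bad <- names(out)[out[out[names(out)]] != out]
  if (length(bad)) stop("alias map not idempotent for: ", paste(bad, collapse = ", "))
  out
}

#' Canonicalize gene identifiers through an alias map
#'
#' Identifiers absent from the map pass through unchanged (case-sensitive
#' matching); with `strict = TRUE` unknown identifiers are an error.
#'
#' @param ids character vector of gene identifiers.
#' @param map alias map from [alias_map()], or `NULL` for pass-through.
#' @param strict error on identifiers not present in the map?
#' @return character vector of canonical ids, same length as `ids`.
#' @export
canonicalize <- function(ids, map = NULL, strict = FALSE) {
  if (is.null(map)) return(ids)
  hit <- ids %in% names(map)
  if (strict && !all(hit))
    stop("unknown gene identifiers under strict alias matching: ",
         paste(unique(ids[!hit]), collapse = ", "))
  ids[hit] <- unname(map[ids[hit]])
  ids
}

# internal: sniff the field delimiter of a delimited text file (tab preferred,
# comma fallback), honouring an explicit override.
detect_delimiter <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  first <- readLines(path, n = 1L)
  if (length(first) && grepl("\t", first)) "\t" else ","
}

# internal: does a first row look like a header? Gene-set and edge files carry
# no standard header; we call a row a header when a cell matches a known
# column word.
looks_like_header <- function(cells) {
  any(tolower(cells) %in% c("gene", "gene_a", "gene_b", "source", "target",
                            "gene_id", "id", "interactor_a", "interactor_b",
                            "species_a", "species_b", "cluster", "cluster_id"))
}

read_delim_raw <- function(path, delimiter = NULL, header = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_delimiter(path, delimiter)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list(rows = list(), sep = sep, skipped_header = FALSE))
  cells <- strsplit(lines, sep, fixed = TRUE)
  cells <- lapply(cells, trimws)
  skip <- if (is.na(header)) looks_like_header(cells[[1]]) else isTRUE(header)
  if (skip) cells <- cells[-1L]
  list(rows = cells, sep = sep, skipped_header = skip, n_lines = length(lines))
}

#' Read a protein-protein interaction edge list
#'
#' Parses a BioGRID-style two-or-more column delimited file into edge records.
#' The first two columns are gene identifiers; any further columns are kept as
#' metadata. Duplicate and reversed rows are preserved here — collapsing them
#' is the graph layer's job ([build_interactome()]).
#'
#' @param path path to a tab- or comma-separated edge file.
#' @param alias_map optional [alias_map()] applied to both gene columns.
#' @param metadata_filter optional named list: column index (3, 4, ...) or
#'   metadata name -> character vector of allowed values. Rows failing any
#'   filter are dropped; the count of dropped rows is recorded in the
#'   `"dropped"` attribute and reported via `message()`.
#' @param delimiter field separator override ("\t" or ","); default sniffs
#'   the first line.
#' @param header `NA` (auto-detect), `TRUE` or `FALSE`.
#' @return a data.frame with columns `gene_a`, `gene_b` and any metadata
#'   columns (`meta1`, `meta2`, ...), with attribute `dropped` (rows removed
#'   by `metadata_filter`).
#' @export
read_edge_list <- function(path, alias_map = NULL, metadata_filter = NULL,
                           delimiter = NULL, header = NA) {
  raw <- read_delim_raw(path, delimiter, header)
  rows <- raw$rows
  if (!length(rows)) stop("no edges: file is empty: ", path)
  nfield <- vapply(rows, length, integer(1))
  offset <- if (raw$skipped_header) 1L else 0L
  if (any(nfield < 2L)) {
    bad <- which(nfield < 2L)[1L]
    stop("edge row with fewer than 2 columns at line ", bad + offset,
         " of ", path)
  }
  ga <- vapply(rows, `[[`, character(1), 1L)
  gb <- vapply(rows, `[[`, character(1), 2L)
  if (any(!nzchar(ga)) || any(!nzchar(gb))) {
    bad <- which(!nzchar(ga) | !nzchar(gb))[1L]
    stop("empty gene identifier at line ", bad + offset, " of ", path)
  }
  nmeta <- max(nfield) - 2L
  df <- data.frame(gene_a = canonicalize(ga, alias_map),
                   gene_b = canonicalize(gb, alias_map),
                   stringsAsFactors = FALSE)
  if (nmeta > 0) {
    for (j in seq_len(nmeta)) {
      df[[paste0("meta", j)]] <-
        vapply(rows, function(r) if (length(r) >= j + 2L) r[[j + 2L]] else NA_character_,
               character(1))
    }
  }
  dropped <- 0L
  if (!is.null(metadata_filter)) {
    keep <- rep(TRUE, nrow(df))
    for (key in names(metadata_filter)) {
      col <- if (grepl("^[0-9]+$", key)) paste0("meta", as.integer(key) - 2L) else key
      if (!col %in% names(df)) stop("metadata_filter names unknown column: ", key)
      keep <- keep & df[[col]] %in% metadata_filter[[key]]
    }
    dropped <- sum(!keep)
    if (dropped > 0)
      message("read_edge_list: dropped ", dropped, " row(s) failing metadata filter")
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
  }
  if (!nrow(df)) stop("no edges: all rows removed by metadata filter: ", path)
  attr(df, "dropped") <- dropped
  df
}

#' Annotated gene sets
#'
#' A gene set is a deduplicated collection of canonical gene ids for one
#' species carrying a free-text role label ("core LAGs", "essential",
#' "clone-available", ...).
#'
#' @param genes character vector of gene ids (duplicates collapsed).
#' @param species non-empty species label, e.g. `"worm"`.
#' @param label free-text role description.
#' @return an object of class `gene_set` with elements `genes`, `species`,
#'   `label`.
#' @export
gene_set <- function(genes, species, label = "") {
  stopifnot(is.character(genes), is_scalar_chr(species))
  if (!nzchar(species)) stop("species label must be non-empty")
  genes <- unique(genes[nzchar(genes)])
  structure(list(genes = genes, species = species, label = label),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$species,
      if (nzchar(x$label)) paste0(" [", x$label, "]"),
      ": ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Read a gene set from a one-column (or first-column) file
#'
#' @inheritParams read_edge_list
#' @param species species label attached to the set.
#' @param label role label attached to the set.
#' @param strict error if any id is missing from `alias_map`.
#' @return a [gene_set()].
#' @export
read_gene_set <- function(path, species, label = "", alias_map = NULL,
                          strict = FALSE, delimiter = NULL, header = NA) {
  raw <- read_delim_raw(path, delimiter, header)
  if (!length(raw$rows)) stop("empty gene-set file: ", path)
  ids <- vapply(raw$rows, `[[`, character(1), 1L)
  ids <- canonicalize(ids, alias_map, strict = strict)
  gene_set(ids, species = species, label = label)
}

#' Orthology maps
#'
#' Many-to-many gene correspondences between two species, InParanoid-cluster
#' style. Pairs are deduplicated; the reverse mapping is the transpose.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b` and optionally
#'   `cluster`.
#' @param species_pair character vector of two species labels `(a, b)`.
#' @return an object of class `orthology_map`.
#' @export
orthology_map <- function(pairs, species_pair = c("a", "b")) {
  stopifnot(is.data.frame(pairs), all(c("gene_a", "gene_b") %in% names(pairs)),
            is.character(species_pair), length(species_pair) == 2)
  if (!"cluster" %in% names(pairs)) pairs$cluster <- NA_character_
  pairs <- unique(pairs[, c("gene_a", "gene_b", "cluster")])
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, species_pair = species_pair),
            class = "orthology_map")
}

#' @export
print.orthology_map <- function(x, ...) {
  cat("<orthology_map> ", x$species_pair[1], " <-> ", x$species_pair[2], ": ",
      nrow(x$pairs), " pairs (", length(unique(x$pairs$gene_a)), " x ",
      length(unique(x$pairs$gene_b)), " genes)\n", sep = "")
  invisible(x)
}

#' Read an orthology table
#'
#' Rows of `(species_a_gene, species_b_gene[, cluster_id])`. Pairs are
#' deduplicated on load.
#'
#' @inheritParams read_edge_list
#' @param species_pair labels of the two species, in file column order.
#' @return an [orthology_map()].
#' @export
read_orthology <- function(path, species_pair = c("a", "b"),
                           delimiter = NULL, header = NA) {
  raw <- read_delim_raw(path, delimiter, header)
  if (!length(raw$rows)) stop("empty orthology file: ", path)
  nfield <- vapply(raw$rows, length, integer(1))
  offset <- if (raw$skipped_header) 1L else 0L
  if (any(nfield < 2L))
    stop("orthology row with one gene at line ", which(nfield < 2L)[1L] + offset,
         " of ", path)
  pairs <- data.frame(
    gene_a = vapply(raw$rows, `[[`, character(1), 1L),
    gene_b = vapply(raw$rows, `[[`, character(1), 2L),
    cluster = vapply(raw$rows, function(r) if (length(r) >= 3L) r[[3L]] else NA_character_,
                     character(1)),
    stringsAsFactors = FALSE)
  orthology_map(pairs, species_pair = species_pair)
}

#' Export a longevity network to GraphML or a TSV edge list
#'
#' GraphML preserves node roles ("core"/"partner") as a node attribute, so the
#' file re-loads to an isomorphic graph with roles intact
#' ([read_network_graphml()]). TSV writes one edge per row.
#'
#' @param network a `longevity_network` (see [build_longevity_network()]).
#' @param path output file path.
#' @param format `"graphml"` or `"tsv"`.
#' @export
write_network <- function(network, path, format = c("graphml", "tsv")) {
  stopifnot(inherits(network, "longevity_network"))
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown format '", format[1],
                                              "'; supported: graphml, tsv"))
  g <- network$graph
  if (igraph::vcount(g) == 0) stop("cannot export an empty network")
  if (format == "graphml") {
    igraph::V(g)$role <- ifelse(igraph::V(g)$name %in% network$core_nodes,
                                "core", "partner")
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    utils::write.table(data.frame(gene_a = el[, 1], gene_b = el[, 2]),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Re-load a GraphML longevity network written by [write_network()]
#'
#' @param path GraphML file path.
#' @return a `longevity_network` with the stored core/partner roles.
#' @export
read_network_graphml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  if (!"role" %in% igraph::vertex_attr_names(g))
    stop("GraphML file lacks the node 'role' attribute: ", path)
  core <- igraph::V(g)$name[igraph::V(g)$role == "core"]
  partners <- igraph::V(g)$name[igraph::V(g)$role == "partner"]
  new_longevity_network(g, core, partners, parent = NULL)
}
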