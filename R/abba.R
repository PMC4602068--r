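#' Retrieve gene sets overlapping a query list
#'
#' Step one of the guilt-by-association walk: find every gene set sharing at
#' least `min_overlap` genes with the query list, either directly or through
#' homology when an index is supplied (the query and all sets are compared in
#' cluster space).
#'
#' @param collection A [gene_set_collection()].
#' @param query_genes Non-empty character vector of query gene identifiers.
#' @param min_overlap Minimum |set ∩ query| to retrieve a set; must not
#'   exceed the query size.
#' @param index Optional [cluster_index()] enabling homology mode. The query
#'   genes are looked up across species (a bare gene list carries no species
#'   tag) and the collection is harmonized before overlaps are counted.
#' @param query_species Species used to synthesize singleton clusters for
#'   query genes absent from the index (homology mode only).
#' @return Character vector of retrieved `set_id`s in collection order.
#' @export
abba_retrieve <- function(collection, query_genes, min_overlap = 1L,
                          index = NULL, query_species = "unknown") {
  stopifnot(inherits(collection, "gene_set_collection"))
  check_tokens(query_genes, "query_genes")
  query_genes <- unique(query_genes)
  if (!is.numeric(min_overlap) || length(min_overlap) != 1L ||
      min_overlap < 1L || min_overlap > length(query_genes)) {
    stop_data(sprintf("min_overlap must lie in [1, %d]", length(query_genes)),
              class = "setweaver_domain_error")
  }
  space <- abba_space(collection, query_genes, index, query_species)
  hits <- vapply(
    space$collection$sets,
    function(gs) length(intersect(gs$members, space$query)) >= min_overlap,
    logical(1L)
  )
  names(space$collection$sets)[hits]
}

#' Rank novel genes by prevalence across retrieved sets
#'
#' Step two of the guilt-by-association walk: over the sets retrieved by
#' [abba_retrieve()], count for each non-query gene the number of supporting
#' sets it appears in (its *prevalence*). The walk is unweighted — every
#' supporting set contributes exactly one, regardless of its size or scores.
#' In homology mode rows are cluster ids and any homolog of a query gene
#' counts as part of the query, so it is never ranked against itself.
#'
#' @inheritParams abba_retrieve
#' @param min_prevalence Drop ranked genes supported by fewer sets (default 1,
#'   i.e. keep all).
#' @return A `ranked_gene_table` tibble with columns `gene_id`, `prevalence`
#'   and `supporting_sets` (list-column of `set_id`s), sorted by descending
#'   prevalence, ties by gene id; empty (with a message) when no set meets the
#'   overlap threshold.
#' @examples
#' col <- gene_set_collection(list(
#'   gene_set("S1", c("g1", "g2", "g4")),
#'   gene_set("S2", c("g2", "g3", "g4", "g5")),
#'   gene_set("S3", c("g5", "g6"))
#' ))
#' abba_rank(col, c("g1", "g2", "g3"), min_overlap = 2)
#' @export
abba_rank <- function(collection, query_genes, min_overlap = 1L,
                      index = NULL, min_prevalence = 1L,
                      query_species = "unknown") {
  retrieved <- abba_retrieve(collection, query_genes, min_overlap,
                             index = index, query_species = query_species)
  space <- abba_space(collection, unique(query_genes), index, query_species)
  empty <- tibble(gene_id = character(), prevalence = integer(),
                  supporting_sets = list())
  if (length(retrieved) == 0L) {
    message("no gene set meets the minimum overlap; returning empty table")
    return(ranked_gene_table(empty))
  }
  support <- lapply(retrieved, function(id) {
    setdiff(space$collection$sets[[id]]$members, space$query)
  })
  names(support) <- retrieved
  long <- bind_rows(Map(function(id, genes) tibble(set_id = id, gene_id = genes),
                        retrieved, support))
  if (nrow(long) == 0L) return(ranked_gene_table(empty))
  out <- summarise(group_by(long, .data$gene_id),
                   prevalence = dplyr::n(),
                   supporting_sets = list(.data$set_id),
                   .groups = "drop")
  out <- out[order(-out$prevalence, out$gene_id, method = "radix"), ]
  out <- out[out$prevalence >= min_prevalence, ]
  ranked_gene_table(out)
}

ranked_gene_table <- function(x) {
  class(x) <- c("ranked_gene_table", setdiff(class(x), "ranked_gene_table"))
  x
}

# Shared query/collection space: raw identifiers, or homology clusters when
# an index is given (one space per run; mixed-space overlap is not defined).
abba_space <- function(collection, query_genes, index, query_species) {
  if (is.null(index)) {
    return(list(collection = collection, query = query_genes))
  }
  stopifnot(inherits(index, "cluster_index"))
  harmonized <- harmonize_collection(collection, index)
  query_clusters <- unique(unlist(lapply(query_genes, function(g) {
    hit <- index$mapping$cluster_id[index$mapping$gene_id == g]
    if (length(hit) == 0L) singleton_cluster(query_species, g) else hit
  }), use.names = FALSE))
  list(collection = harmonized, query = query_clusters)
}
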