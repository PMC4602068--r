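#' Gene connectivity (degree) table for a collection
#'
#' A gene's degree in the bipartite membership graph is the number of
#' collection sets containing it; highly connected genes recur across many
#' independent experiments and are the hub candidates of the collection. The
#' fraction of sets is reported alongside, the form used when summarising
#' hits such as "present in 70% of the retrieved results". When the
#' collection is harmonized, degrees count sets per homology cluster.
#'
#' @param collection A non-empty [gene_set_collection()].
#' @return Tibble with one row per universe gene: `gene_id`, `degree`,
#'   `fraction_of_sets`, sorted by descending degree, ties by gene id.
#' @export
degree_table <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(collection$sets) == 0L) stop_data("collection is empty")
  occ <- table(unlist(lapply(collection$sets, `[[`, "members"),
               use.names = FALSE))
  out <- tibble(
    gene_id = names(occ),
    degree = as.integer(occ),
    fraction_of_sets = as.integer(occ) / length(collection$sets)
  )
  out <- out[order(-out$degree, out$gene_id, method = "radix"), ]
  class(out) <- c("degree_table", class(out))
  out
}

#' Minimum-degree bipartite subgraph (hub-gene view)
#'
#' Restricts the bipartite gene-set graph to genes meeting a user-defined
#' minimum degree, the gene set graph view that pushes the most highly
#' connected genes to the fore. Set nodes are always retained — even when
#' every one of their genes falls below threshold — so exports show which
#' sets contributed nothing above it.
#'
#' @param collection A non-empty [gene_set_collection()].
#' @param min_degree Minimum number of containing sets for a gene node
#'   (≥ 1); `1` keeps the full graph.
#' @return A `gene_set_graph` object with `set_nodes` (all `set_id`s),
#'   `gene_nodes` (tibble `gene_id`, `degree`, ordered ascending by degree so
#'   the highest-degree genes come last), `edges` (membership pairs among kept
#'   genes) and `threshold`.
#' @export
threshold_subgraph <- function(collection, min_degree = 1L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!is.numeric(min_degree) || length(min_degree) != 1L || min_degree < 1L) {
    stop_data("min_degree must be a count >= 1")
  }
  deg <- degree_table(collection)
  kept <- deg[deg$degree >= min_degree, c("gene_id", "degree")]
  kept <- kept[order(kept$degree, kept$gene_id, method = "radix"), ]
  long <- as_tibble(collection)[, c("set_id", "gene_id")]
  edges <- long[long$gene_id %in% kept$gene_id, ]
  structure(
    list(
      set_nodes = set_ids(collection),
      gene_nodes = kept,
      edges = edges,
      threshold = as.integer(min_degree)
    ),
    class = "gene_set_graph"
  )
}

#' @export
print.gene_set_graph <- function(x, ...) {
  cat(sprintf(
    "<gene_set_graph> %d set node%s, %d gene node%s at degree >= %d, %d edges\n",
    length(x$set_nodes), if (length(x$set_nodes) == 1L) "" else "s",
    nrow(x$gene_nodes), if (nrow(x$gene_nodes) == 1L) "" else "s",
    x$threshold, nrow(x$edges)
  ))
  invisible(x)
}
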