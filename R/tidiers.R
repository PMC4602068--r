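#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a gene set collection
#'
#' @param x A [gene_set_collection()].
#' @param ... Unused.
#' @return One row per set: `set_id`, `name`, `abbreviation`, `species`,
#'   `tier`, `n_genes`, `harmonized`.
#' @export
tidy.gene_set_collection <- function(x, ...) {
  bind_rows(lapply(x$sets, function(gs) {
    tibble(
      set_id = gs$set_id, name = gs$name, abbreviation = gs$abbreviation,
      species = gs$species, tier = gs$tier,
      n_genes = length(gs$members),
      harmonized = isTRUE(gs$harmonized)
    )
  }))
}

#' Collection-level summary
#'
#' @param x A [gene_set_collection()].
#' @param ... Unused.
#' @return One-row tibble: `n_sets`, `n_genes`, `n_memberships`, `density`
#'   (filled fraction of the bipartite incidence), `n_species`, `harmonized`.
#' @export
glance.gene_set_collection <- function(x, ...) {
  uni <- universe(x)
  memb <- sum(vapply(x$sets, function(gs) length(gs$members), integer(1L)))
  tibble(
    n_sets = length(x$sets),
    n_genes = length(uni),
    n_memberships = memb,
    density = if (length(x$sets) > 0L && length(uni) > 0L) {
      memb / (length(x$sets) * length(uni))
    } else NA_real_,
    n_species = length(unique(vapply(x$sets, `[[`, character(1L), "species"))),
    harmonized = is_harmonized(x)
  )
}

#' Tidy a hierarchical similarity DAG
#'
#' @param x A [build_hisim_dag()] result.
#' @param ... Unused.
#' @return One row per node: `node_id`, `level`, `label`, `n_sets`,
#'   `n_shared_genes`, `n_emphasis`, `is_leaf`.
#' @export
tidy.hisim_dag <- function(x, ...) {
  mutate(
    x$nodes[, c("node_id", "level", "label", "is_leaf")],
    n_sets = x$nodes$level,
    n_shared_genes = vapply(x$nodes$shared_genes, length, integer(1L)),
    n_emphasis = vapply(x$nodes$emphasis, length, integer(1L))
  )
}

#' DAG-level summary
#'
#' @param x A [build_hisim_dag()] result.
#' @param ... Unused.
#' @return One-row tibble: `n_nodes`, `n_leaves`, `n_edges`, `max_level`,
#'   `n_emphasis_nodes`.
#' @export
glance.hisim_dag <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_leaves = sum(x$nodes$is_leaf),
    n_edges = nrow(x$edges),
    max_level = if (nrow(x$nodes)) max(x$nodes$level) else 0L,
    n_emphasis_nodes = sum(vapply(x$nodes$emphasis, length, integer(1L)) > 0L)
  )
}

#' Tidy a thresholded gene-set graph
#'
#' @param x A [threshold_subgraph()] result.
#' @param ... Unused.
#' @return The gene-node tibble (`gene_id`, `degree`), ascending by degree.
#' @export
tidy.gene_set_graph <- function(x, ...) as_tibble(x$gene_nodes)

#' Graph-level summary
#'
#' @param x A [threshold_subgraph()] result.
#' @param ... Unused.
#' @return One-row tibble: `n_set_nodes`, `n_gene_nodes`, `n_edges`,
#'   `threshold`.
#' @export
glance.gene_set_graph <- function(x, ...) {
  tibble(
    n_set_nodes = length(x$set_nodes),
    n_gene_nodes = nrow(x$gene_nodes),
    n_edges = nrow(x$edges),
    threshold = x$threshold
  )
}

#' Tidy a homology cluster index
#'
#' @param x A [cluster_index()].
#' @param ... Unused.
#' @return The mapping tibble (`cluster_id`, `species`, `gene_id`).
#' @export
tidy.cluster_index <- function(x, ...) as_tibble(x$mapping)

#' Cluster-index summary
#'
#' @param x A [cluster_index()].
#' @param ... Unused.
#' @return One-row tibble: `n_clusters`, `n_mappings`, `n_species`.
#' @export
glance.cluster_index <- function(x, ...) {
  tibble(
    n_clusters = length(unique(x$mapping$cluster_id)),
    n_mappings = nrow(x$mapping),
    n_species = length(unique(x$mapping$species))
  )
}
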