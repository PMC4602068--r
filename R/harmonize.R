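#' Build a homology cluster index
#'
#' Cross-species comparability is achieved by mapping species-tagged gene
#' identifiers into homology *clusters*: groups of genes across species
#' treated as equivalent (HomoloGene-style many-to-many homology, represented
#' via clusters rather than pairwise ortholog edges). Each (species, gene)
#' pair maps to at most one cluster; when the input assigns a gene to several
#' clusters, the first occurrence wins and a warning reports the conflict.
#'
#' @param data Data frame with columns `cluster_id`, `species`, `gene_id`.
#' @return A `cluster_index` object.
#' @seealso [read_homology_tsv()], [harmonize_collection()]
#' @export
cluster_index <- function(data = NULL) {
  if (is.null(data)) {
    data <- tibble(cluster_id = character(), species = character(),
                   gene_id = character())
  }
  data <- as_tibble(data)
  need <- c("cluster_id", "species", "gene_id")
  if (!all(need %in% names(data))) {
    stop_data(sprintf("homology table must have columns %s",
                      paste(need, collapse = ", ")),
              class = "setweaver_schema_error")
  }
  data <- data[need]
  data <- distinct(data)
  key <- paste(data$species, data$gene_id, sep = "\x1f")
  dup <- duplicated(key)
  if (any(dup)) {
    warn(sprintf(
      "%d (species, gene) pair(s) assigned to multiple clusters; keeping first occurrence (e.g. %s/%s)",
      sum(dup), data$species[dup][1L], data$gene_id[dup][1L]
    ))
    data <- data[!dup, ]
    key <- key[!dup]
  }
  structure(
    list(
      mapping = data,
      lookup = setNames(data$cluster_id, key)
    ),
    class = "cluster_index"
  )
}

#' @export
print.cluster_index <- function(x, ...) {
  cat(sprintf(
    "<cluster_index> %d clusters, %d (species, gene) mappings, %d species\n",
    length(unique(x$mapping$cluster_id)), nrow(x$mapping),
    length(unique(x$mapping$species))
  ))
  invisible(x)
}

#' @export
length.cluster_index <- function(x) length(unique(x$mapping$cluster_id))

# Cluster id for one (species, gene); NA when unmapped.
cluster_of <- function(index, species, gene) {
  unname(index$lookup[paste(species, gene, sep = "\x1f")])
}

# All genes (any species) sharing a homology cluster with `gene`, looked up
# across species since a bare gene query carries no species tag.
cluster_cognates <- function(index, gene) {
  hit <- index$mapping$cluster_id[index$mapping$gene_id == gene]
  if (length(hit) == 0L) return(character())
  sw_sort(index$mapping$gene_id[index$mapping$cluster_id %in% hit])
}

# Deterministic cluster id synthesized for a gene absent from the index, so
# harmonization is total: unmapped genes become singleton clusters.
singleton_cluster <- function(species, gene) {
  paste("u", species, gene, sep = ":")
}

#' Map a gene set into homology-cluster space
#'
#' Replaces each member gene by its homology cluster id. Genes absent from
#' the index become deterministic singleton clusters (`"u:<species>:<gene>"`),
#' so the operation never drops genes. Within-species paralogs falling in the
#' same cluster collapse to one node; set `collapse = FALSE` to keep
#' species-qualified singleton nodes instead. When scored paralogs collapse,
#' the best score is kept (`score_polarity = "min"` for p-value-like scores,
#' `"max"` for correlation-like magnitudes).
#'
#' @param gs A [gene_set()].
#' @param index A [cluster_index()].
#' @param collapse Collapse members mapping to the same cluster (default TRUE).
#' @param score_polarity `"min"` or `"max"`: which collapsed score survives.
#' @return A harmonized `gene_set` whose members are cluster ids. Harmonizing
#'   an already-harmonized set is the identity.
#' @export
map_to_clusters <- function(gs, index, collapse = TRUE, score_polarity = "min") {
  stopifnot(inherits(gs, "gene_set"), inherits(index, "cluster_index"))
  score_polarity <- match.arg(score_polarity, c("min", "max"))
  if (isTRUE(gs$harmonized)) return(gs)
  mapped <- cluster_of(index, gs$species, gs$members)
  miss <- is.na(mapped)
  mapped[miss] <- if (collapse) {
    singleton_cluster(gs$species, gs$members[miss])
  } else {
    # without collapsing every node stays species-qualified, mapped or not
    gs$members[miss]
  }
  if (!collapse) {
    mapped[!miss] <- paste(gs$species, gs$members[!miss], sep = ":")
  }
  scores <- NULL
  if (!is.null(gs$scores)) {
    per_gene <- unname(gs$scores[match(gs$members, names(gs$scores))])
    agg <- tapply(per_gene, mapped, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0L) NA_real_
      else if (score_polarity == "min") min(v) else max(v)
    })
    agg <- agg[!is.na(agg)]
    if (length(agg) > 0L) scores <- setNames(as.numeric(agg), names(agg))
  }
  members <- mapped[!duplicated(mapped)]
  out <- gene_set(
    gs$set_id, members,
    name = gs$name, abbreviation = gs$abbreviation,
    description = gs$description, species = gs$species, tier = gs$tier,
    scores = scores
  )
  out$harmonized <- TRUE
  out
}

#' Harmonize a whole collection into cluster space
#'
#' Maps every set via [map_to_clusters()] and recomputes the universe in
#' cluster space, making cross-species sets directly comparable: two sets of
#' orthologous genes from different species become identical cluster sets.
#' Idempotent: harmonizing twice equals harmonizing once. With an empty index
#' every gene becomes its own singleton cluster, a relabeling under which
#' every downstream statistic is unchanged.
#'
#' @inheritParams map_to_clusters
#' @param collection A [gene_set_collection()].
#' @return A harmonized `gene_set_collection`.
#' @export
harmonize_collection <- function(collection, index, collapse = TRUE,
                                 score_polarity = "min") {
  stopifnot(inherits(collection, "gene_set_collection"))
  out <- collection
  out$sets <- lapply(collection$sets, map_to_clusters,
                     index = index, collapse = collapse,
                     score_polarity = score_polarity)
  out
}

is_harmonized <- function(collection) {
  length(collection$sets) > 0L &&
    all(vapply(collection$sets, function(gs) isTRUE(gs$harmonized), logical(1L)))
}
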