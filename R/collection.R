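#' Create a gene set
#'
#' A gene set is an identified, species-tagged collection of gene identifiers
#' with optional per-gene association scores (p-values, correlations, ...) and
#' curation-tier metadata. Gene identifiers are opaque, case-sensitive tokens;
#' cross-species comparability comes from mapping them into homology-cluster
#' space (see [harmonize_collection()]), not from normalising the tokens.
#'
#' @param set_id Unique token identifying the set within a collection.
#' @param members Character vector of gene identifiers; duplicates are
#'   collapsed, first occurrence kept.
#' @param name,description Free-text metadata.
#' @param abbreviation Short label used in graph node labels.
#' @param species Species tag (free token, e.g. `"mouse"`, `"human"`).
#' @param tier Curation tier, one of `"I"` (curated resource) through `"V"`
#'   (private upload).
#' @param scores Optional named numeric vector of per-gene association scores;
#'   names must be members of the set.
#' @return A `gene_set` object.
#' @examples
#' gene_set("gs1", c("Gnb1", "Kcnj9"), species = "mouse", tier = "III")
#' @export
gene_set <- function(set_id, members, name = set_id, abbreviation = set_id,
                     description = "", species = "unknown", tier = "V",
                     scores = NULL) {
  if (!is_token(set_id)) stop_data("set_id must be a single non-empty token without whitespace")
  check_tokens(members, "members")
  members <- members[!duplicated(members)]
  if (!is_token(species)) stop_data("species must be a single non-empty token")
  tier <- as.character(tier)
  if (length(tier) != 1L || !tier %in% TIERS) {
    stop_data(sprintf("tier must be one of %s", paste(TIERS, collapse = ", ")))
  }
  if (!is.null(scores)) {
    if (!is.numeric(scores) || is.null(names(scores))) {
      stop_data("scores must be a named numeric vector")
    }
    extra <- setdiff(names(scores), members)
    if (length(extra) > 0L) {
      stop_data(sprintf(
        "scores keyed by non-members: %s", paste(head(extra, 3L), collapse = ", ")
      ))
    }
    scores <- scores[!duplicated(names(scores))]
  }
  structure(
    list(
      set_id = set_id, name = as.character(name)[1L],
      abbreviation = as.character(abbreviation)[1L],
      description = as.character(description)[1L],
      species = species, tier = tier,
      members = members, scores = scores,
      harmonized = FALSE
    ),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf(
    "<gene_set> %s (%s, Tier %s%s): %d gene%s\n",
    x$set_id, x$species, x$tier,
    if (isTRUE(x$harmonized)) ", harmonized" else "",
    length(x$members), if (length(x$members) == 1L) "" else "s"
  ))
  shown <- head(x$members, 8L)
  cat("  ", paste(shown, collapse = " "),
      if (length(x$members) > 8L) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Create a collection of gene sets
#'
#' A collection is the substrate of every analysis in the package: it induces
#' a bipartite graph whose two vertex classes are the gene sets and the union
#' of their genes (the *universe*), with an edge for each set membership.
#' Insertion order of sets is preserved so that every derived table and export
#' is deterministic.
#'
#' @param sets A list of [gene_set()] objects with pairwise-distinct `set_id`s.
#' @return A `gene_set_collection` object.
#' @examples
#' col <- gene_set_collection(list(
#'   gene_set("A", c("g1", "g2")),
#'   gene_set("B", c("g2", "g3"))
#' ))
#' universe(col)
#' @export
gene_set_collection <- function(sets = list()) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  stopifnot(is.list(sets))
  col <- structure(list(sets = list()), class = "gene_set_collection")
  for (gs in sets) col <- add_geneset(col, gs)
  col
}

#' Add a gene set to a collection
#'
#' @param collection A [gene_set_collection()].
#' @param gs A [gene_set()] whose `set_id` is not yet in the collection.
#' @return The updated collection; the universe is always recomputed from the
#'   member lists, never stored stale.
#' @export
add_geneset <- function(collection, gs) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!inherits(gs, "gene_set")) stop_data("gs must be a gene_set")
  if (gs$set_id %in% names(collection$sets)) {
    stop_data(
      sprintf("set_id '%s' already present in collection", gs$set_id),
      class = "setweaver_duplicate_id"
    )
  }
  collection$sets[[gs$set_id]] <- gs
  collection
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Gene universe of a collection
#'
#' @param collection A [gene_set_collection()].
#' @return Sorted character vector: the union of all member lists.
#' @export
universe <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  sw_sort(unlist(lapply(collection$sets, `[[`, "members"), use.names = FALSE))
}

set_ids <- function(collection) names(collection$sets)

get_set <- function(collection, id) {
  gs <- collection$sets[[id]]
  if (is.null(gs)) {
    stop_data(sprintf("no gene set with set_id '%s'", id),
              class = "setweaver_lookup_error")
  }
  gs
}

#' @export
print.gene_set_collection <- function(x, ...) {
  uni <- universe(x)
  cat(sprintf(
    "<gene_set_collection> %d set%s over %d gene%s\n",
    length(x$sets), if (length(x$sets) == 1L) "" else "s",
    length(uni), if (length(uni) == 1L) "" else "s"
  ))
  for (gs in head(x$sets, 6L)) {
    cat(sprintf("  %s [%s, Tier %s] %d genes\n",
                gs$set_id, gs$species, gs$tier, length(gs$members)))
  }
  if (length(x$sets) > 6L) cat(sprintf("  ... and %d more\n", length(x$sets) - 6L))
  invisible(x)
}

#' Long-form membership table of a collection
#'
#' @param x A `gene_set_collection`.
#' @param ... Unused.
#' @return A tibble with columns `set_id`, `gene_id` and `score` (`NA` where no
#'   association score is stored), one row per bipartite membership edge.
#' @export
as_tibble.gene_set_collection <- function(x, ...) {
  rows <- lapply(x$sets, function(gs) {
    score <- rep(NA_real_, length(gs$members))
    if (!is.null(gs$scores)) {
      idx <- match(gs$members, names(gs$scores))
      score <- unname(gs$scores[idx])
    }
    tibble(set_id = gs$set_id, gene_id = gs$members, score = score)
  })
  bind_rows(rows)
}

#' Build a collection from a long-form membership table
#'
#' The tabular twin of [gene_set_collection()]: one row per (set, gene) pair,
#' the carrier used by the long-form TSV reader so per-gene association scores
#' survive (GMT cannot carry scores).
#'
#' @param data Data frame with columns `set_id`, `gene_id` and optionally
#'   `score`.
#' @param metadata Optional data frame keyed by `set_id` with any of `name`,
#'   `abbreviation`, `description`, `species`, `tier`.
#' @param species,tier Defaults for sets absent from `metadata`.
#' @return A `gene_set_collection`.
#' @export
collection_from_table <- function(data, metadata = NULL,
                                  species = "unknown", tier = "V") {
  data <- as_tibble(data)
  if (!all(c("set_id", "gene_id") %in% names(data))) {
    stop_data("data must have columns set_id and gene_id",
              class = "setweaver_schema_error")
  }
  meta_of <- function(id, field, default) {
    if (is.null(metadata) || !field %in% names(metadata)) return(default)
    hit <- metadata[[field]][match(id, metadata$set_id)]
    if (is.na(hit)) default else hit
  }
  ids <- unique(data$set_id)
  sets <- lapply(ids, function(id) {
    rows <- data[data$set_id == id, ]
    scores <- NULL
    if ("score" %in% names(rows) && any(!is.na(rows$score))) {
      keep <- !is.na(rows$score) & !duplicated(rows$gene_id)
      scores <- setNames(rows$score[keep], rows$gene_id[keep])
    }
    gene_set(
      id, rows$gene_id,
      name = meta_of(id, "name", id),
      abbreviation = meta_of(id, "abbreviation", id),
      description = meta_of(id, "description", ""),
      species = meta_of(id, "species", species),
      tier = meta_of(id, "tier", tier),
      scores = scores
    )
  })
  gene_set_collection(sets)
}

#' Filter a collection by curation tier
#'
#' Curation tiers grade provenance: Tier I is data from curated resources
#' (e.g. model-organism database annotations), Tier II data derived from
#' operations on resource data, Tier III literature-curated or reviewed
#' submissions, Tier IV unreviewed public submissions, and Tier V private
#' uploads.
#'
#' @param collection A [gene_set_collection()].
#' @param tiers Non-empty character vector of tiers to keep.
#' @return The sub-collection of sets whose tier is in `tiers`, order
#'   preserved; possibly empty.
#' @export
filter_by_tier <- function(collection, tiers) {
  stopifnot(inherits(collection, "gene_set_collection"))
  tiers <- as.character(tiers)
  if (length(tiers) == 0L) stop_data("tiers must be non-empty")
  if (!all(tiers %in% TIERS)) {
    stop_data(sprintf("unknown tier(s): %s",
                      paste(setdiff(tiers, TIERS), collapse = ", ")))
  }
  keep <- vapply(collection$sets, function(gs) gs$tier %in% tiers, logical(1L))
  out <- collection
  out$sets <- collection$sets[keep]
  out
}

#' Search a collection by gene and/or free text
#'
#' Finds the gene sets containing a query gene (or any homolog, when a
#' [cluster_index()] is supplied) and/or whose name or description contains a
#' query string. When both criteria are given the match is their conjunction,
#' supporting queries such as a gene symbol AND a phenotype keyword. Text
#' matching is plain case-insensitive substring, not tokenized.
#'
#' @param collection A [gene_set_collection()].
#' @param gene Optional gene identifier to look up by identity or shared
#'   homology cluster.
#' @param text Optional free-text query over `name` + `description`.
#' @param index Optional [cluster_index()]; when supplied, sets containing any
#'   gene in the same homology cluster as `gene` also match.
#' @return Character vector of matching `set_id`s in collection order
#'   (unranked; empty when nothing matches).
#' @export
search_sets <- function(collection, gene = NULL, text = NULL, index = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.null(gene) && is.null(text)) {
    stop_data("supply at least one of gene or text")
  }
  keep <- rep(TRUE, length(collection$sets))
  if (!is.null(gene)) {
    if (!is_token(gene)) stop_data("gene must be a single token")
    targets <- gene
    if (!is.null(index)) {
      targets <- unique(c(targets, cluster_cognates(index, gene)))
    }
    keep <- keep & vapply(
      collection$sets,
      function(gs) any(targets %in% gs$members),
      logical(1L)
    )
  }
  if (!is.null(text)) {
    pat <- tolower(as.character(text)[1L])
    keep <- keep & vapply(
      collection$sets,
      function(gs) grepl(pat, tolower(paste(gs$name, gs$description)), fixed = TRUE),
      logical(1L)
    )
  }
  names(collection$sets)[keep]
}
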