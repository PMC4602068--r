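#' Jaccard similarity of two gene sets
#'
#' The Jaccard index |A ∩ B| / |A ∪ B| measures set similarity on \[0, 1\];
#' it is 1 exactly when the member sets are identical and 0 when disjoint.
#' Both sets must live in the same gene space: compare raw identifiers, or
#' harmonize both sides first ([harmonize_collection()]) for cross-species
#' comparisons.
#'
#' @param a,b [gene_set()] objects.
#' @return One-row tibble with `set_a`, `set_b`, `intersection_size`,
#'   `union_size`, `jaccard`.
#' @examples
#' jaccard(gene_set("A", c("a", "b", "c")), gene_set("B", c("b", "c", "d")))
#' @export
jaccard <- function(a, b) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  if (length(a$members) == 0L && length(b$members) == 0L) {
    stop_data("Jaccard similarity is undefined for two empty sets")
  }
  i <- length(intersect(a$members, b$members))
  u <- length(union(a$members, b$members))
  tibble(
    set_a = a$set_id, set_b = b$set_id,
    intersection_size = i, union_size = u,
    jaccard = i / u
  )
}

#' Pairwise Jaccard similarities across a collection
#'
#' All unordered pairs, or — in query mode — every other set against one
#' user-selected set, the typical "find sets similar to mine" workflow.
#'
#' @param collection A [gene_set_collection()] with at least two sets.
#' @param query Optional `set_id`; when given, only pairs involving it are
#'   returned (n − 1 rows).
#' @return Tibble of Jaccard results sorted by descending `jaccard`, ties
#'   broken by set ids.
#' @export
jaccard_matrix <- function(collection, query = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  ids <- set_ids(collection)
  if (!is.null(query)) {
    get_set(collection, query)  # surfaces lookup error
    pairs <- data.frame(a = query, b = setdiff(ids, query))
  } else {
    if (length(ids) < 2L) {
      stop_data("jaccard_matrix needs at least two sets")
    }
    pairs <- as.data.frame(t(utils::combn(ids, 2L)))
    names(pairs) <- c("a", "b")
  }
  out <- bind_rows(Map(
    function(a, b) jaccard(get_set(collection, a), get_set(collection, b)),
    pairs$a, pairs$b
  ))
  out <- arrange(out, desc(.data$jaccard), .data$set_a, .data$set_b)
  class(out) <- c("setweaver_jaccard", class(out))
  out
}

#' Exact hypergeometric overlap test for two gene sets
#'
#' Tests whether two sets share more genes than expected when drawing at
#' random from a common universe: with N universe genes of which K lie in set
#' `a`, drawing the n genes of set `b` yields k = |a ∩ b| overlaps; the
#' p-value is the exact upper tail P(X ≥ k) of the hypergeometric
#' distribution (enrichment only — no depletion test). The default universe
#' is the collection-wide gene universe; supply `universe` to use a custom
#' background.
#'
#' @param a,b [gene_set()] objects whose members lie in `universe`.
#' @param universe Character vector of background genes.
#' @return One-row tibble with `set_a`, `set_b`, `population_size`,
#'   `successes`, `draws`, `observed` and `p_value`.
#' @examples
#' u <- paste0("g", 1:10)
#' hypergeometric_test(gene_set("A", u[1:5]), gene_set("B", u[1:5]), u)
#' @export
hypergeometric_test <- function(a, b, universe) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  universe <- unique(universe)
  if (!all(a$members %in% universe) || !all(b$members %in% universe)) {
    stop_data("universe must contain every member of both sets",
              class = "setweaver_domain_error")
  }
  N <- length(universe)
  K <- length(a$members)
  n <- length(b$members)
  k <- length(intersect(a$members, b$members))
  # exact upper tail; phyper sums the pmf, no normal approximation
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  tibble(
    set_a = a$set_id, set_b = b$set_id,
    population_size = N, successes = K, draws = n, observed = k,
    p_value = p
  )
}

#' Pairwise hypergeometric overlap tests across a collection
#'
#' Every unordered pair (or each pair involving `query`) is tested against
#' the shared universe; Benjamini–Hochberg q-values accompany the raw
#' p-values.
#'
#' @inheritParams jaccard_matrix
#' @param universe Background gene vector; defaults to the collection
#'   universe.
#' @return Tibble sorted by ascending `p_value` with a `q_value` column.
#' @export
hypergeom_matrix <- function(collection, query = NULL, universe = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- universe %||% universe(collection)
  ids <- set_ids(collection)
  if (!is.null(query)) {
    get_set(collection, query)
    pairs <- data.frame(a = query, b = setdiff(ids, query))
  } else {
    if (length(ids) < 2L) stop_data("hypergeom_matrix needs at least two sets")
    pairs <- as.data.frame(t(utils::combn(ids, 2L)))
    names(pairs) <- c("a", "b")
  }
  out <- bind_rows(Map(
    function(a, b) hypergeometric_test(get_set(collection, a),
                                       get_set(collection, b), universe),
    pairs$a, pairs$b
  ))
  out$q_value <- p.adjust(out$p_value, method = "BH")
  arrange(out, .data$p_value, .data$set_a, .data$set_b)
}

#' Genes in the intersection of several sets
#'
#' @param collection A [gene_set_collection()].
#' @param sets Character vector of at least two `set_id`s; default all sets.
#' @return Sorted character vector of genes present in every named set
#'   (possibly empty).
#' @export
intersection_members <- function(collection, sets = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  sets <- sets %||% set_ids(collection)
  if (length(sets) < 2L) stop_data("intersection needs at least two sets")
  member_lists <- lapply(sets, function(id) get_set(collection, id)$members)
  sw_sort(Reduce(intersect, member_lists))
}

#' Boolean combination of gene sets
#'
#' Derives a new gene set by Boolean algebra over existing ones: the union of
#' all inputs, the genes appearing in at least `k` of the inputs, or the
#' difference of a base set minus all others. The derived set records its
#' parent `set_id`s in its description and `parents` attribute (provenance).
#'
#' @param collection A [gene_set_collection()].
#' @param sets Character vector of input `set_id`s (≥ 1).
#' @param mode `"union"`, `"intersect"` (at-least-k occurrence) or
#'   `"difference"`.
#' @param k For `mode = "intersect"`: minimum number of input sets a gene
#'   must appear in, `1 ≤ k ≤ length(sets)`; defaults to all of them (the
#'   plain k-way intersection).
#' @param base For `mode = "difference"`: the `set_id` (must be among `sets`)
#'   whose genes are kept unless present in any other input.
#' @param set_id Identifier for the derived set; a deterministic default is
#'   built from the mode and parents.
#' @return A `gene_set` (possibly with zero qualifying genes, in which case an
#'   error is raised since gene sets must be non-empty).
#' @export
boolean_combine <- function(collection, sets,
                            mode = c("union", "intersect", "difference"),
                            k = NULL, base = NULL, set_id = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  mode <- match.arg(mode)
  if (length(sets) < 1L) stop_data("sets must name at least one gene set")
  member_lists <- lapply(sets, function(id) get_set(collection, id)$members)
  names(member_lists) <- sets
  members <- switch(
    mode,
    union = sw_sort(unlist(member_lists, use.names = FALSE)),
    intersect = {
      k <- k %||% length(sets)
      if (!is.numeric(k) || length(k) != 1L || k < 1L || k > length(sets)) {
        stop_data(sprintf("k must lie in [1, %d]", length(sets)),
                  class = "setweaver_domain_error")
      }
      occ <- table(unlist(lapply(member_lists, unique), use.names = FALSE))
      sw_sort(names(occ)[occ >= k])
    },
    difference = {
      base <- base %||% sets[[1L]]
      if (!base %in% sets) {
        stop_data("base must be one of the input sets",
                  class = "setweaver_domain_error")
      }
      others <- unlist(member_lists[setdiff(sets, base)], use.names = FALSE)
      sw_sort(setdiff(member_lists[[base]], others))
    }
  )
  if (length(members) == 0L) {
    stop_data(sprintf("boolean %s over {%s} yields no genes", mode,
                      paste(sets, collapse = ", ")),
              class = "setweaver_empty_result")
  }
  id <- set_id %||% paste(c(mode, sets), collapse = "_")
  out <- gene_set(
    id, members,
    name = sprintf("Boolean %s of %d sets", mode, length(sets)),
    description = sprintf("derived by %s from: %s", mode,
                          paste(sets, collapse = ", ")),
    species = get_set(collection, sets[[1L]])$species,
    tier = "V"
  )
  attr(out, "parents") <- sets
  out
}
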