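#' Enumerate maximal bicliques of the gene-set bipartite graph
#'
#' A biclique is a group of gene sets together with a group of genes contained
#' in every one of them; it is *maximal* when it can be extended in neither
#' dimension — the shared genes are exactly the full intersection of the sets
#' (gene-maximal) and no further set contains all the shared genes
#' (set-maximal). Maximal bicliques are exactly the closed (set-group,
#' gene-group) pairs of the membership relation, so they are enumerated by
#' closing the distinct per-gene set signatures (the sets each gene belongs
#' to) under intersection; each closed set-group pairs with the genes whose
#' signature contains it. This is complete and duplicate-free without
#' touching the exponential lattice of all set subsets.
#'
#' @param collection A non-empty [gene_set_collection()].
#' @param min_level Minimum number of sets per biclique (default 2: pairwise
#'   and higher intersections).
#' @return Tibble with columns `level` (number of sets), `set_ids` (list of
#'   sorted character vectors) and `shared_genes` (list of sorted character
#'   vectors), ordered by level then lexicographically by set ids.
#' @examples
#' col <- gene_set_collection(list(
#'   gene_set("A", c("g1", "g2")),
#'   gene_set("B", c("g2", "g3"))
#' ))
#' enumerate_maximal_bicliques(col)
#' @export
enumerate_maximal_bicliques <- function(collection, min_level = 2L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(collection$sets) == 0L) stop_data("collection is empty")
  ids <- set_ids(collection)
  genes <- universe(collection)
  # membership incidence: rows genes, cols sets
  inc <- vapply(collection$sets, function(gs) genes %in% gs$members,
                logical(length(genes)))
  if (length(genes) == 1L) inc <- matrix(inc, nrow = 1L, dimnames = list(genes, ids))
  # distinct gene signatures as sorted set-id vectors
  sigs <- unique(apply(inc, 1L, function(r) paste(sw_sort(ids[r]), collapse = "\x1f")))
  sig_list <- lapply(strsplit(sigs, "\x1f", fixed = TRUE), sw_sort)
  # close under pairwise intersection to a fixpoint
  closed <- new.env(parent = emptyenv())
  for (s in sig_list) assign(paste(s, collapse = "\x1f"), s, envir = closed)
  frontier <- sig_list
  while (length(frontier) > 0L) {
    fresh <- list()
    existing <- as.list(closed)
    for (f in frontier) {
      for (e in existing) {
        x <- intersect(f, e)
        if (length(x) == 0L) next
        key <- paste(x, collapse = "\x1f")
        if (!exists(key, envir = closed, inherits = FALSE)) {
          assign(key, x, envir = closed)
          fresh[[length(fresh) + 1L]] <- x
        }
      }
    }
    frontier <- fresh
  }
  groups <- as.list(closed)
  keep <- vapply(groups, length, integer(1L)) >= min_level
  groups <- groups[keep]
  if (length(groups) == 0L) {
    return(tibble(level = integer(), set_ids = list(), shared_genes = list()))
  }
  shared <- lapply(groups, function(p) {
    cols <- match(p, ids)
    hit <- rowSums(inc[, cols, drop = FALSE]) == length(cols)
    genes[hit]
  })
  nonempty <- vapply(shared, length, integer(1L)) > 0L
  groups <- groups[nonempty]
  shared <- shared[nonempty]
  out <- tibble(
    level = unname(vapply(groups, length, integer(1L))),
    set_ids = unname(groups),
    shared_genes = unname(lapply(shared, sw_sort))
  )
  key <- vapply(out$set_ids, paste, character(1L), collapse = "\x1f")
  out[order(out$level, key, method = "radix"), ]
}

#' Build the hierarchical gene-set similarity DAG
#'
#' Arranges individual gene sets and all their maximal multi-way
#' intersections into a leveled directed acyclic graph: the input sets sit at
#' the leaves (level 1, always included even when wholly contained in another
#' set), two-way, three-way, ..., n-way maximal intersections at successively
#' higher levels. Edges are the Hasse relation — the transitive reduction of
#' strict inclusion on the set-id groups — so each leaf points to the
#' smallest intersections it participates in. Nodes are flagged with any
#' *emphasis genes* (a user-selected highlight list) found among their shared
#' genes.
#'
#' @param collection A non-empty [gene_set_collection()].
#' @param emphasis Character vector of genes to highlight wherever they occur.
#' @return A `hisim_dag` object with `nodes` (tibble: `node_id`, `level`,
#'   `label`, `set_ids`, `shared_genes`, `emphasis` list-columns, `is_leaf`)
#'   and `edges` (tibble: `from`, `to` node ids, child-to-parent in
#'   increasing level).
#' @export
build_hisim_dag <- function(collection, emphasis = character()) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(collection$sets) == 0L) stop_data("collection is empty")
  bic <- enumerate_maximal_bicliques(collection, min_level = 2L)
  leaves <- tibble(
    level = 1L,
    set_ids = lapply(set_ids(collection), identity),
    shared_genes = lapply(collection$sets, function(gs) sw_sort(gs$members)),
    label = vapply(collection$sets, `[[`, character(1L), "abbreviation"),
    is_leaf = TRUE
  )
  higher <- mutate(
    bic,
    label = vapply(.data$set_ids, function(p) {
      paste(vapply(p, function(id) get_set(collection, id)$abbreviation,
                   character(1L)), collapse = "+")
    }, character(1L)),
    is_leaf = FALSE
  )
  nodes <- bind_rows(leaves, higher)
  nodes$node_id <- vapply(nodes$set_ids, paste, character(1L), collapse = "+")
  nodes$emphasis <- lapply(nodes$shared_genes, function(g) sw_sort(intersect(g, emphasis)))
  nodes <- nodes[, c("node_id", "level", "label", "set_ids", "shared_genes",
                     "emphasis", "is_leaf")]
  edges <- hasse_edges(nodes$set_ids, nodes$node_id)
  structure(list(nodes = nodes, edges = edges), class = "hisim_dag")
}

# Transitive reduction of strict inclusion over set-id groups: keep u -> v
# (u a proper subset of v) only when no w nests strictly between them.
hasse_edges <- function(groups, node_ids) {
  n <- length(groups)
  sub <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j &&
          length(groups[[i]]) < length(groups[[j]]) &&
          all(groups[[i]] %in% groups[[j]])) {
        sub[i, j] <- TRUE
      }
    }
  }
  from <- character(); to <- character()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (!sub[i, j]) next
      between <- any(sub[i, ] & sub[, j])
      if (!between) {
        from <- c(from, node_ids[i])
        to <- c(to, node_ids[j])
      }
    }
  }
  ord <- order(match(from, node_ids), match(to, node_ids))
  tibble(from = from[ord], to = to[ord])
}

#' @export
print.hisim_dag <- function(x, ...) {
  cat(sprintf(
    "<hisim_dag> %d nodes (%d leaves, max level %d), %d edges\n",
    nrow(x$nodes), sum(x$nodes$is_leaf),
    if (nrow(x$nodes)) max(x$nodes$level) else 0L, nrow(x$edges)
  ))
  flagged <- sum(vapply(x$nodes$emphasis, length, integer(1L)) > 0L)
  if (flagged > 0L) cat(sprintf("  %d node(s) carry emphasis genes\n", flagged))
  invisible(x)
}
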