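# Independent brute-force oracles used to validate the fast implementations.
# All deliberately naive: exhaustive subset scans and direct joins.

# Every non-empty subset of sets is checked for a non-empty full intersection
# and two-sided maximality (no further set contains the whole intersection;
# shared genes are exactly the full intersection by construction).
oracle_bicliques <- function(collection, min_level = 2L) {
  ids <- names(collection$sets)
  members <- lapply(collection$sets, `[[`, "members")
  out <- list()
  for (size in seq(min_level, length(ids))) {
    for (sub in utils::combn(ids, size, simplify = FALSE)) {
      shared <- Reduce(intersect, members[sub])
      if (length(shared) == 0L) next
      others <- setdiff(ids, sub)
      extendable <- any(vapply(others, function(o) all(shared %in% members[[o]]),
                               logical(1L)))
      if (!extendable) {
        out[[length(out) + 1L]] <- list(
          set_ids = sort(sub, method = "radix"),
          shared_genes = sort(shared, method = "radix")
        )
      }
    }
  }
  key <- vapply(out, function(x) paste(x$set_ids, collapse = "\x1f"), character(1L))
  out[order(vapply(out, function(x) length(x$set_ids), integer(1L)),
            key, method = "radix")]
}

# Exact upper-tail overlap probability by enumerating every possible draw of
# n genes from the N-gene universe and counting those with >= k successes.
oracle_hypergeom_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)  # one column per draw
  mean(colSums(draws <= K) >= k)
}

# Seeded Monte-Carlo estimate of the same tail probability.
oracle_hypergeom_mc <- function(N, K, n, k, B = 1e5L) {
  hits <- 0L
  for (b in seq_len(B)) {
    if (sum(sample.int(N, n) <= K) >= k) hits <- hits + 1L
  }
  hits / B
}

# Brute-force guilt-by-association: scan all sets for the overlap threshold,
# then tally every non-query gene over the retrieved sets.
oracle_abba <- function(collection, query_genes, min_overlap) {
  ids <- names(collection$sets)
  retrieved <- ids[vapply(ids, function(id) {
    length(intersect(collection$sets[[id]]$members, query_genes)) >= min_overlap
  }, logical(1L))]
  tally <- list()
  for (id in retrieved) {
    for (g in setdiff(collection$sets[[id]]$members, query_genes)) {
      tally[[g]] <- c(tally[[g]], id)
    }
  }
  if (length(tally) == 0L) {
    return(data.frame(gene_id = character(), prevalence = integer()))
  }
  df <- data.frame(
    gene_id = names(tally),
    prevalence = vapply(tally, length, integer(1L)),
    row.names = NULL
  )
  df[order(-df$prevalence, df$gene_id, method = "radix"), , drop = FALSE]
}

# Direct join + per-(term, gene) distinct-publication count.
oracle_term_members <- function(gene_pub, pub_term, min_pubs) {
  gene_pub <- unique(gene_pub[, c("gene_id", "pub_id")])
  pub_term <- unique(pub_term[, c("pub_id", "term")])
  out <- list()
  for (tm in sort(unique(pub_term$term), method = "radix")) {
    pubs <- pub_term$pub_id[pub_term$term == tm]
    genes <- unique(gene_pub$gene_id)
    keep <- vapply(genes, function(g) {
      length(unique(intersect(gene_pub$pub_id[gene_pub$gene_id == g], pubs))) >= min_pubs
    }, logical(1L))
    if (any(keep)) out[[tm]] <- sort(genes[keep], method = "radix")
  }
  out
}

# Small random collection with controlled size, for property tests.
random_collection <- function(n_sets, n_genes, seed,
                              min_size = 1L, max_size = NULL) {
  max_size <- max_size %||% n_genes
  genes <- sprintf("g%02d", seq_len(n_genes))
  withr::with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) {
      size <- sample(seq(min_size, max_size), 1L)
      gene_set(sprintf("S%02d", i), sample(genes, size))
    })
  })
  gene_set_collection(sets)
}

`%||%` <- rlang::`%||%`
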