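#' Build term-associated gene sets from literature association tables
#'
#' Joins a gene-to-publication table with a publication-to-term table (the
#' gene2pubmed / MeSH-annotation pattern) to form one gene set per term. To
#' reduce annotation artifacts a gene joins a term's set only when it occurs
#' in at least `min_pubs` *distinct* publications tagged with that term;
#' duplicated input rows are collapsed before counting, so they never inflate
#' evidence. Terms with no qualifying gene are omitted. Note the resulting
#' sets reflect literature coverage: a missing gene is absence of evidence,
#' not evidence of absence, and no correction for literature bias is applied.
#'
#' @param gene_pub Data frame with columns `gene_id`, `pub_id`.
#' @param pub_term Data frame with columns `pub_id`, `term`.
#' @param min_pubs Minimum distinct supporting publications per (gene, term)
#'   association (default 2).
#' @param species,tier Metadata stamped on every derived set (derived-from-
#'   resource data defaults to Tier II).
#' @return A [gene_set_collection()] with one set per surviving term, terms
#'   in sorted order, members sorted; each description records `min_pubs`.
#' @export
build_term_genesets <- function(gene_pub, pub_term, min_pubs = 2L,
                                species = "unknown", tier = "II") {
  gene_pub <- as_tibble(gene_pub)
  pub_term <- as_tibble(pub_term)
  if (!all(c("gene_id", "pub_id") %in% names(gene_pub))) {
    stop_data("gene_pub must have columns gene_id, pub_id",
              class = "setweaver_schema_error")
  }
  if (!all(c("pub_id", "term") %in% names(pub_term))) {
    stop_data("pub_term must have columns pub_id, term",
              class = "setweaver_schema_error")
  }
  if (!is.numeric(min_pubs) || length(min_pubs) != 1L || min_pubs < 1L) {
    stop_data("min_pubs must be a count >= 1")
  }
  gene_pub <- distinct(gene_pub[, c("gene_id", "pub_id")])
  pub_term <- distinct(pub_term[, c("pub_id", "term")])
  joined <- inner_join(gene_pub, pub_term, by = "pub_id",
                       relationship = "many-to-many")
  counts <- summarise(group_by(joined, .data$term, .data$gene_id),
                      n_pubs = dplyr::n_distinct(.data$pub_id),
                      .groups = "drop")
  counts <- counts[counts$n_pubs >= min_pubs, ]
  sets <- lapply(sw_sort(counts$term), function(tm) {
    gene_set(
      tm, sw_sort(counts$gene_id[counts$term == tm]),
      name = tm,
      description = sprintf(
        "genes with >= %d supporting publication(s) annotated to term %s",
        min_pubs, tm
      ),
      species = species, tier = tier
    )
  })
  gene_set_collection(sets)
}
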