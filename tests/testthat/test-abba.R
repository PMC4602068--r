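worked_example <- function() {
  gene_set_collection(list(
    gene_set("S1", c("g1", "g2", "g4")),
    gene_set("S2", c("g2", "g3", "g4", "g5")),
    gene_set("S3", c("g5", "g6"))
  ))
}

test_that("retrieval honours the minimum-overlap threshold", {
  col <- worked_example()
  q <- c("g1", "g2", "g3")
  expect_equal(abba_retrieve(col, q, min_overlap = 2), c("S1", "S2"))
  expect_equal(abba_retrieve(col, q, min_overlap = 3), character())
  expect_true(all(abba_retrieve(col, q, 2) %in% abba_retrieve(col, q, 1)))
  expect_error(abba_retrieve(col, q, min_overlap = 4),
               class = "setweaver_domain_error")
  expect_error(abba_retrieve(col, q, min_overlap = 0),
               class = "setweaver_domain_error")
})

test_that("ranking counts supporting sets, excludes query genes, breaks ties by id", {
  col <- worked_example()
  r <- abba_rank(col, c("g1", "g2", "g3"), min_overlap = 2)
  expect_equal(r$gene_id, c("g4", "g5"))
  expect_equal(r$prevalence, c(2L, 1L))
  expect_equal(r$supporting_sets[[1]], c("S1", "S2"))
  expect_equal(r$supporting_sets[[2]], "S2")
  expect_false(any(c("g1", "g2", "g3") %in% r$gene_id))
  expect_equal(r$prevalence, vapply(r$supporting_sets, length, integer(1L)))

  expect_message(
    empty <- abba_rank(col, c("x1", "x2"), min_overlap = 1),
    "no gene set"
  )
  expect_equal(nrow(empty), 0L)

  filtered <- abba_rank(col, c("g1", "g2", "g3"), min_overlap = 2,
                        min_prevalence = 2)
  expect_equal(filtered$gene_id, "g4")
})

test_that("ranking equals the brute-force oracle and is monotone in the threshold", {
  for (seed in 1:40) {
    withr::with_seed(seed, {
      n_sets <- sample(2:10, 1)
      n_genes <- sample(5:30, 1)
      q_size <- sample(2:5, 1)
    })
    col <- random_collection(n_sets, n_genes, seed + 3000)
    query <- withr::with_seed(seed + 4000,
                              sample(sprintf("g%02d", seq_len(n_genes)), q_size))
    prev_by_gene <- NULL
    for (m in seq_len(min(3L, q_size))) {
      got <- suppressMessages(abba_rank(col, query, min_overlap = m))
      want <- oracle_abba(col, query, m)
      expect_equal(got$gene_id, want$gene_id)
      expect_equal(got$prevalence, want$prevalence)
      if (!is.null(prev_by_gene)) {
        # raising the overlap threshold never increases any gene's prevalence,
        # and never surfaces a gene absent at the lower threshold
        now <- setNames(got$prevalence, got$gene_id)
        expect_true(all(got$gene_id %in% names(prev_by_gene)))
        expect_true(all(now <= prev_by_gene[names(now)]))
      }
      prev_by_gene <- setNames(got$prevalence, got$gene_id)
    }
  }
})

test_that("homology mode counts overlap in cluster space and excludes query homologs", {
  col <- gene_set_collection(list(
    gene_set("M", c("Gm1", "Gm2", "Gm3"), species = "mouse"),
    gene_set("H", c("GH1", "GH4"), species = "human")
  ))
  idx <- cluster_index(data.frame(
    cluster_id = c("c1", "c1", "c2", "c3", "c4", "c4"),
    species = c("mouse", "human", "mouse", "mouse", "human", "mouse"),
    gene_id = c("Gm1", "GH1", "Gm2", "Gm3", "GH4", "Gm4")
  ))
  # without homology the human set shares nothing with a mouse query
  expect_equal(abba_retrieve(col, "Gm1", 1), "M")
  # with homology GH1 ~ Gm1, so the human set is retrieved too
  expect_equal(abba_retrieve(col, "Gm1", 1, index = idx), c("M", "H"))
  r <- abba_rank(col, "Gm1", 1, index = idx)
  # rows are cluster ids; the query cluster c1 is excluded
  expect_false("c1" %in% r$gene_id)
  expect_setequal(r$gene_id, c("c2", "c3", "c4"))
  expect_equal(r$prevalence[r$gene_id == "c4"], 1L)
})
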