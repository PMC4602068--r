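test_that("collections track their universe as the union of member lists", {
  col <- gene_set_collection()
  col <- add_geneset(col, gene_set("A", "g1"))
  expect_equal(universe(col), "g1")

  col <- add_geneset(col, gene_set("B", c("g2", "g3")))
  col <- add_geneset(col, gene_set("C", c("g2", "g1")))
  expect_equal(universe(col), c("g1", "g2", "g3"))
  expect_length(col, 3L)

  # universe recomputed after every mutation, for arbitrary orders of addition
  for (seed in 1:5) {
    sets <- withr::with_seed(seed, {
      lapply(1:6, function(i) gene_set(paste0("S", i),
                                       sample(sprintf("g%02d", 1:15), 4)))
    })
    col2 <- gene_set_collection()
    expected <- character()
    for (gs in sets) {
      col2 <- add_geneset(col2, gs)
      expected <- sort(union(expected, gs$members), method = "radix")
      expect_equal(universe(col2), expected)
    }
  }
})

test_that("duplicate set ids and malformed inputs are rejected", {
  col <- gene_set_collection(gene_set("A", "g1"))
  expect_error(add_geneset(col, gene_set("A", "g9")),
               class = "setweaver_duplicate_id")
  expect_error(gene_set("bad id", "g1"), class = "setweaver_data_error")
  expect_error(gene_set("A", character()), class = "setweaver_data_error")
  expect_error(gene_set("A", c("g1", "g 2")), class = "setweaver_data_error")
  expect_error(gene_set("A", "g1", tier = "VI"), class = "setweaver_data_error")
  expect_error(gene_set("A", "g1", scores = c(gX = 0.1)),
               class = "setweaver_data_error")
})

test_that("tier filtering keeps the requested tiers in order and composes by intersection", {
  col <- gene_set_collection(list(
    gene_set("A", "g1", tier = "I"),
    gene_set("B", "g2", tier = "III"),
    gene_set("C", "g3", tier = "V"),
    gene_set("D", "g4", tier = "III")
  ))
  expect_equal(names(filter_by_tier(col, "III")$sets), c("B", "D"))
  expect_length(filter_by_tier(col, "II"), 0L)

  all_i <- gene_set_collection(list(gene_set("X", "g1", tier = "I")))
  expect_identical(filter_by_tier(all_i, "I"), all_i)

  # filtering twice equals filtering by the tier intersection
  t1 <- c("I", "III")
  t2 <- c("III", "V")
  expect_identical(
    filter_by_tier(filter_by_tier(col, t1), t2),
    filter_by_tier(col, intersect(t1, t2))
  )
  expect_error(filter_by_tier(col, character()), class = "setweaver_data_error")
})

test_that("search matches by gene, homolog, and free text, conjunctively", {
  col <- gene_set_collection(list(
    gene_set("A", c("g1", "g2"), description = "alcohol preference in BXD mice"),
    gene_set("B", c("g1", "g3"), description = "nicotine response"),
    gene_set("C", c("GH", "g4"), species = "human",
             description = "Alcohol dependence GWAS")
  ))
  expect_equal(search_sets(col, gene = "g1"), c("A", "B"))
  expect_equal(search_sets(col, text = "alcohol"), c("A", "C"))
  expect_equal(search_sets(col, gene = "g1", text = "alcohol"), "A")
  expect_equal(search_sets(col, text = "zebrafish"), character())
  expect_error(search_sets(col), class = "setweaver_data_error")

  # homology: a mouse query gene finds the set holding its human cognate
  idx <- cluster_index(data.frame(
    cluster_id = c("c1", "c1"), species = c("mouse", "human"),
    gene_id = c("Gm", "GH")
  ))
  expect_equal(search_sets(col, gene = "Gm", index = idx), "C")
  expect_equal(search_sets(col, gene = "Gm"), character())

  # conjunction is a subset of each single-criterion search
  both <- search_sets(col, gene = "g1", text = "response")
  expect_true(all(both %in% search_sets(col, gene = "g1")))
  expect_true(all(both %in% search_sets(col, text = "response")))
})

test_that("long-form table round-trips through a collection with scores", {
  tbl <- tibble::tibble(
    set_id = c("A", "A", "B"),
    gene_id = c("g1", "g2", "g2"),
    score = c(0.01, 0.2, NA)
  )
  col <- collection_from_table(
    tbl,
    metadata = data.frame(set_id = "A", species = "mouse", tier = "III")
  )
  expect_equal(col$sets$A$species, "mouse")
  expect_equal(col$sets$A$tier, "III")
  expect_equal(col$sets$B$tier, "V")
  expect_equal(col$sets$A$scores, c(g1 = 0.01, g2 = 0.2))
  expect_equal(tibble::as_tibble(col), tbl)
})
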