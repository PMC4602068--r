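test_that("maximal bicliques match hand-derived cases", {
  col <- gene_set_collection(list(
    gene_set("A", c("g1", "g2")), gene_set("B", c("g2", "g3"))
  ))
  b <- enumerate_maximal_bicliques(col)
  expect_equal(nrow(b), 1L)
  expect_equal(b$set_ids[[1]], c("A", "B"))
  expect_equal(b$shared_genes[[1]], "g2")

  disjoint <- gene_set_collection(list(
    gene_set("A", "g1"), gene_set("B", "g2"), gene_set("C", "g3")
  ))
  expect_equal(nrow(enumerate_maximal_bicliques(disjoint)), 0L)

  # all three sets share g1: the 2-way subsets are non-maximal
  same <- gene_set_collection(list(
    gene_set("A", "g1"), gene_set("B", "g1"), gene_set("C", "g1")
  ))
  b3 <- enumerate_maximal_bicliques(same)
  expect_equal(nrow(b3), 1L)
  expect_equal(b3$set_ids[[1]], c("A", "B", "C"))
  expect_equal(b3$level, 3L)
})

test_that("enumeration equals the exhaustive subset-testing oracle", {
  for (seed in 1:40) {
    withr::with_seed(seed, {
      n_sets <- sample(2:8, 1)
      n_genes <- sample(3:20, 1)
    })
    col <- random_collection(n_sets, n_genes, seed + 1000)
    got <- enumerate_maximal_bicliques(col)
    want <- oracle_bicliques(col)
    expect_equal(nrow(got), length(want))
    expect_equal(got$set_ids, lapply(want, `[[`, "set_ids"))
    expect_equal(got$shared_genes, lapply(want, `[[`, "shared_genes"))
  }
})

test_that("the similarity DAG has leaves for inputs and Hasse edges only", {
  col <- gene_set_collection(list(
    gene_set("A", c("g1", "g2")), gene_set("B", c("g2", "g3"))
  ))
  dag <- build_hisim_dag(col, emphasis = "g2")
  expect_equal(nrow(dag$nodes), 3L)
  expect_equal(nrow(dag$edges), 2L)
  expect_setequal(dag$edges$from, c("A", "B"))
  expect_true(all(dag$edges$to == "A+B"))
  # emphasis flagged on the shared node and on both leaves containing g2
  flagged <- dag$nodes$node_id[vapply(dag$nodes$emphasis, length, integer(1L)) > 0L]
  expect_setequal(flagged, c("A", "B", "A+B"))

  single <- build_hisim_dag(gene_set_collection(gene_set("A", "g1")))
  expect_equal(nrow(single$nodes), 1L)
  expect_equal(nrow(single$edges), 0L)
})

test_that("DAG edges are the transitive reduction of strict set inclusion", {
  for (seed in 1:25) {
    withr::with_seed(seed, {
      n_sets <- sample(2:7, 1)
      n_genes <- sample(3:15, 1)
    })
    col <- random_collection(n_sets, n_genes, seed + 2000)
    dag <- build_hisim_dag(col)
    groups <- dag$nodes$set_ids
    names(groups) <- dag$nodes$node_id
    strict_sub <- function(u, v) length(u) < length(v) && all(u %in% v)
    # recompute the expected reduction naively
    want_from <- character(); want_to <- character()
    for (i in names(groups)) for (j in names(groups)) {
      if (i == j || !strict_sub(groups[[i]], groups[[j]])) next
      between <- any(vapply(names(groups), function(w) {
        w != i && w != j && strict_sub(groups[[i]], groups[[w]]) &&
          strict_sub(groups[[w]], groups[[j]])
      }, logical(1L)))
      if (!between) { want_from <- c(want_from, i); want_to <- c(want_to, j) }
    }
    got <- paste(dag$edges$from, dag$edges$to, sep = "->")
    want <- paste(want_from, want_to, sep = "->")
    expect_setequal(got, want)

    # leaves are exactly the input sets; graph is acyclic; edges increase level
    expect_setequal(dag$nodes$node_id[dag$nodes$is_leaf], names(col$sets))
    g <- as_igraph(dag)
    expect_true(igraph::is_dag(g))
    lvl <- setNames(dag$nodes$level, dag$nodes$node_id)
    expect_true(all(lvl[dag$edges$from] < lvl[dag$edges$to]))
    # along every edge the parent intersection's genes nest in the child leaf/node
    sg <- dag$nodes$shared_genes
    names(sg) <- dag$nodes$node_id
    for (e in seq_len(nrow(dag$edges))) {
      expect_true(all(sg[[dag$edges$to[e]]] %in% sg[[dag$edges$from[e]]]))
    }
  }
})
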