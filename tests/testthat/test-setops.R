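test_that("Jaccard similarity matches hand-enumerated values and its invariants", {
  a <- gene_set("A", c("a", "b", "c"))
  b <- gene_set("B", c("b", "c", "d"))
  expect_equal(jaccard(a, b)$jaccard, 0.5)
  expect_equal(jaccard(a, b)$intersection_size, 2L)
  expect_equal(jaccard(a, b)$union_size, 4L)

  expect_equal(jaccard(a, gene_set("A2", c("c", "a", "b")))$jaccard, 1)
  expect_equal(jaccard(a, gene_set("D", c("x", "y")))$jaccard, 0)

  # symmetric, bounded, 1 iff identical membership
  for (seed in 1:20) {
    col <- random_collection(2, 8, seed)
    x <- col$sets[[1]]; y <- col$sets[[2]]
    jxy <- jaccard(x, y); jyx <- jaccard(y, x)
    expect_equal(jxy$jaccard, jyx$jaccard)
    expect_gte(jxy$jaccard, 0)
    expect_lte(jxy$jaccard, 1)
    expect_equal(jxy$jaccard == 1, setequal(x$members, y$members))
    expect_gte(jxy$union_size, max(length(x$members), length(y$members)))
  }
})

test_that("jaccard_matrix covers all pairs, supports query mode, and sorts", {
  col <- gene_set_collection(list(
    gene_set("A", c("g1", "g2")), gene_set("B", c("g1", "g2")),
    gene_set("C", c("g1", "g2")), gene_set("D", c("g9"))
  ))
  m <- jaccard_matrix(col)
  expect_equal(nrow(m), choose(4, 2))
  expect_true(all(m$jaccard[m$set_a %in% c("A", "B", "C") &
                            m$set_b %in% c("A", "B", "C")] == 1))
  expect_false(is.unsorted(rev(m$jaccard)))

  q <- jaccard_matrix(col, query = "A")
  expect_equal(nrow(q), 3L)
  expect_true(all(q$set_a == "A" | q$set_b == "A"))
  expect_error(jaccard_matrix(col, query = "nope"),
               class = "setweaver_lookup_error")
  expect_error(jaccard_matrix(gene_set_collection(gene_set("A", "g1"))),
               class = "setweaver_data_error")
})

test_that("k-way intersections enumerate exactly", {
  col <- gene_set_collection(list(
    gene_set("A", c("a", "b")), gene_set("B", c("b", "c")),
    gene_set("C", c("x", "y"))
  ))
  expect_equal(intersection_members(col, c("A", "B")), "b")
  expect_equal(intersection_members(col, c("A", "C")), character())
  expect_equal(intersection_members(col), character())
  expect_error(intersection_members(col, "A"), class = "setweaver_data_error")
})

test_that("hypergeometric test is exact against closed forms and enumeration", {
  u10 <- paste0("g", 1:10)
  # complete containment: p = 1 / C(10,5) = 1/252
  res <- hypergeometric_test(gene_set("A", u10[1:5]), gene_set("B", u10[1:5]), u10)
  expect_equal(res$p_value, 1 / choose(10, 5))
  expect_equal(res$observed, 5L)

  # zero overlap: P(X >= 0) = 1
  res0 <- hypergeometric_test(gene_set("A", u10[1:5]),
                              gene_set("B", u10[6:10]), u10)
  expect_equal(res0$p_value, 1)

  # N=4, K=2, n=2, k=1 -> 5/6 by enumerating all 6 draws
  u4 <- paste0("g", 1:4)
  res1 <- hypergeometric_test(gene_set("A", u4[1:2]),
                              gene_set("B", u4[2:3]), u4)
  expect_equal(res1$p_value, 5 / 6)
  expect_equal(res1$p_value, oracle_hypergeom_enum(4, 2, 2, 1))

  # random small instances against full enumeration of draws
  for (seed in 1:15) {
    withr::with_seed(seed, {
      N <- sample(6:18, 1); K <- sample(1:N, 1); n <- sample(1:min(5, N), 1)
    })
    uni <- paste0("g", seq_len(N))
    a <- gene_set("A", uni[seq_len(K)])
    b <- gene_set("B", withr::with_seed(seed + 1, sample(uni, n)))
    k <- length(intersect(a$members, b$members))
    expect_equal(
      hypergeometric_test(a, b, uni)$p_value,
      oracle_hypergeom_enum(N, K, n, k),
      tolerance = 1e-12
    )
  }

  expect_error(
    hypergeometric_test(gene_set("A", u10[1:5]), gene_set("B", u10[1:5]), u10[1:3]),
    class = "setweaver_domain_error"
  )
})

test_that("hypergeom_matrix reports BH q-values over all pairs", {
  col <- random_collection(5, 12, seed = 2)
  m <- hypergeom_matrix(col)
  expect_equal(nrow(m), choose(5, 2))
  expect_equal(m$q_value, p.adjust(m$p_value, method = "BH"))
  expect_false(is.unsorted(m$p_value))
})

test_that("Boolean combinations follow union / at-least-k / difference semantics", {
  col <- gene_set_collection(list(
    gene_set("A", c("a", "b")), gene_set("B", c("b", "c")),
    gene_set("C", c("b"))
  ))
  expect_equal(boolean_combine(col, c("A", "B", "C"), "intersect", k = 2)$members, "b")
  expect_equal(boolean_combine(col, c("A", "B"), "union")$members, c("a", "b", "c"))
  expect_equal(boolean_combine(col, "A", "union")$members, c("a", "b"))
  expect_equal(boolean_combine(col, c("A", "B"), "difference", base = "A")$members, "a")
  expect_error(boolean_combine(col, c("A", "B"), "intersect", k = 3),
               class = "setweaver_domain_error")
  expect_error(boolean_combine(col, c("A", "B"), "difference", base = "C"),
               class = "setweaver_domain_error")
  expect_equal(attr(boolean_combine(col, c("A", "B"), "union"), "parents"),
               c("A", "B"))

  # at-least-all-k equals the plain intersection; monotone non-increasing in k
  for (seed in 1:10) {
    colr <- random_collection(4, 10, seed)
    ids <- names(colr$sets)
    bool_all <- tryCatch(
      boolean_combine(colr, ids, "intersect", k = 4, set_id = "x")$members,
      setweaver_empty_result = function(e) character()
    )
    expect_equal(bool_all, intersection_members(colr, ids))
    sizes <- vapply(1:4, function(k) {
      res <- tryCatch(
        length(boolean_combine(colr, ids, "intersect", k = k)$members),
        setweaver_empty_result = function(e) 0L
      )
      res
    }, integer(1L))
    expect_false(is.unsorted(rev(sizes)))
  }
})

test_that("set operations are invariant under input order", {
  col <- random_collection(4, 10, seed = 8)
  ids <- names(col$sets)
  perm <- rev(ids)
  expect_equal(intersection_members(col, ids), intersection_members(col, perm))
  expect_equal(
    boolean_combine(col, ids, "union", set_id = "u1")$members,
    boolean_combine(col, perm, "union", set_id = "u1")$members
  )
})
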