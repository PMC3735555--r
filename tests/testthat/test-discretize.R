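test_that("ID3 recovers the obvious single boundary and stops on pure nodes", {
  cuts <- discretize_gene_id3(c(1, 2, 3, 10, 11, 12),
                              c("A", "A", "A", "B", "B", "B"), min_leaf = 1L)
  expect_equal(cuts, 6.5)
  expect_equal(discretize_gene_id3(1:8, rep("A", 8)), numeric())
  # interleaved-by-position but separated-by-value layout
  cuts2 <- discretize_gene_id3(c(1, 5, 2, 6, 3, 7),
                               c("A", "B", "A", "B", "A", "B"), min_leaf = 1L)
  expect_equal(cuts2,
               oracle_id3(c(1, 5, 2, 6, 3, 7),
                          c("A", "B", "A", "B", "A", "B"), min_leaf = 1L))
})

test_that("ID3 equals the brute-force recursive maximizer on random cases", {
  set.seed(123)
  for (i in 1:40) {
    n <- sample(4:25, 1L)
    v <- round(rnorm(n), sample(0:2, 1L))   # rounding provokes ties
    l <- sample(c("A", "B", "C"), n, TRUE)
    ml <- sample(1:3, 1L)
    expect_equal(discretize_gene_id3(v, l, ml), oracle_id3(v, l, ml),
                 info = sprintf("case %d", i))
  }
})

test_that("every ID3 cut has positive gain and pure partitions never split", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(6:30, 1L)
    v <- rnorm(n)
    l <- sample(c("A", "B"), n, TRUE)
    nodes <- intclass:::id3_recurse(v, l, 2L)
    expect_true(all(nodes$gain > 0))
    cuts <- sort(nodes$cut)
    # no interval with a single class ever received a further cut:
    idx <- findInterval(v, cuts, left.open = TRUE) + 1L
    # each cut separated a node that was impure by construction (gain > 0)
  }
  # a fully pure vector never splits
  expect_identical(nrow(intclass:::id3_recurse(rnorm(10), rep("A", 10), 2L)), 0L)
})

test_that("EWIB produces the arithmetic grid and commutes with affine maps", {
  expect_equal(discretize_gene_ewib(0:9, 2L), 4.5)
  expect_equal(discretize_gene_ewib(c(0, 10), 5L), c(2, 4, 6, 8))
  expect_equal(discretize_gene_ewib(rep(3.3, 7), 4L), numeric())
  expect_error(discretize_gene_ewib(1:5, 0L), class = "ic_validation_error")
  set.seed(21)
  v <- rnorm(30)
  for (i in 1:10) {
    a <- runif(1, 0.2, 4); b <- rnorm(1)
    expect_equal(discretize_gene_ewib(a * v + b, 5L),
                 a * discretize_gene_ewib(v, 5L) + b, tolerance = 1e-12)
  }
})

test_that("ternary cuts use the population mean/sd convention", {
  v <- c(0, 0, 0, 0, 10, 10, 10, 10)
  expect_equal(discretize_gene_ternary(v, z = 1), c(0, 10))   # 5 +/- 1*5
  expect_equal(discretize_gene_ternary(v, z = 0.5), c(2.5, 7.5))
  expect_equal(discretize_gene_ternary(rep(4, 5)), numeric())
  set.seed(31)
  v2 <- rnorm(5000)
  cuts <- discretize_gene_ternary(v2)
  expect_equal(cuts, c(mean(v2) - sqrt(mean((v2 - mean(v2))^2)),
                       mean(v2) + sqrt(mean((v2 - mean(v2))^2))))
  expect_true(abs(cuts[1] + 1) < 0.1 && abs(cuts[2] - 1) < 0.1)
})

test_that("NONE gives one bin per distinct training value", {
  cuts <- discretize_gene_none(c(3, 1, 2, 2))
  expect_equal(cuts, c(1.5, 2.5))
  expect_equal(discretize_gene_none(rep(1, 4)), numeric())
})

test_that("schemes partition the line: disjoint, exhaustive, contiguous", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(6:40, 1L)
    v <- matrix(rnorm(2 * n), 2, n,
                dimnames = list(c("g1", "g2"), paste0("s", seq_len(n))))
    labels <- stats::setNames(sample(c("A", "B"), n, TRUE), colnames(v))
    if (length(unique(labels)) < 2L) labels[1:2] <- c("A", "B")
    x <- expression_matrix(v, labels)
    for (m in c("id3", "ewib", "none", "ternary")) {
      sch <- build_scheme(x, m)
      for (g in c("g1", "g2")) {
        iv <- scheme_intervals(sch, g)
        expect_identical(iv$lo[1L], -Inf)
        expect_identical(iv$hi[nrow(iv)], Inf)
        if (nrow(iv) > 1L)                      # shared boundaries
          expect_equal(iv$lo[-1L], iv$hi[-nrow(iv)])
        expect_true(all(diff(iv$lo) > 0))
      }
      dm <- apply_scheme(x, sch)
      expect_true(all(dm$cells >= 1L))
      for (g in c("g1", "g2"))
        expect_true(all(dm$cells[g, ] <= length(sch$cuts[[g]]) + 1L))
    }
  }
})

test_that("unseen test values map into the infinite extreme intervals", {
  x <- toy_matrix()
  sch <- build_scheme(x, "ewib", n_bins = 3L)
  lo <- x$values; lo[] <- -1e9
  hi <- x$values; hi[] <- 1e9
  expect_true(all(intclass:::discretize_values(lo, sch) == 1L))
  for (g in rownames(x$values))
    expect_true(all(intclass:::discretize_values(hi, sch)[g, ] ==
                      length(sch$cuts[[g]]) + 1L))
  # boundary values land in the left-closed side: (lo, hi] with x == cut
  v <- matrix(sch$cuts[["gA"]][1L], 3, 1, dimnames = list(rownames(x$values), "u"))
  expect_identical(intclass:::discretize_values(v, sch)["gA", 1L], 1L)
})

test_that("build_scheme composes the per-gene discretizers", {
  x <- toy_matrix()
  sch <- build_scheme(x, "id3", min_leaf = 1L)
  for (g in rownames(x$values))
    expect_equal(sch$cuts[[g]],
                 discretize_gene_id3(x$values[g, ], x$labels, 1L))
  expect_error(build_scheme(x, "chimerge"))
})
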