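test_that("support counts superset transactions", {
  mat <- rbind(c(TRUE, TRUE), c(FALSE, TRUE))
  colnames(mat) <- c("a#1", "b#1")
  db <- as_transaction_db(mat)
  expect_equal(support(character(), db), 1)
  expect_equal(support("a#1", db), 0.5)
  expect_equal(support(c("a#1", "b#1"), db), 0.5)
  expect_equal(support("zz#1", db), 0)
  # anti-monotonicity on random databases
  set.seed(13)
  for (i in 1:20) {
    m <- random_db_matrix(8, 6)
    db <- as_transaction_db(m)
    keys <- colnames(m)
    x <- sample(keys, 2)
    y <- sample(keys, 2)
    expect_lte(support(union(x, y), db), support(x, db))
  }
})

test_that("transactions hold one item per gene and reflect the cells", {
  x <- toy_matrix()
  dm <- apply_scheme(x, build_scheme(x, "ewib", n_bins = 2L))
  db <- build_transactions(dm, "A")
  expect_identical(db$n, 2L)
  expect_true(all(rowSums(db$mat) == nrow(dm$cells)))  # one item per gene
  genes <- intclass:::split_items(colnames(db$mat))$gene
  for (i in seq_len(nrow(db$mat)))
    expect_false(anyDuplicated(genes[db$mat[i, ]]) > 0)
  expect_error(build_transactions(dm, "Z"), class = "ic_validation_error")
})

test_that("minimal-interval-size filtering drops low-coverage items", {
  set.seed(3)
  mat <- matrix(FALSE, 40, 3, dimnames = list(NULL, c("a#1", "b#1", "c#1")))
  mat[1L, "a#1"] <- TRUE                    # 1/40 = 0.025 coverage
  mat[1:10, "b#1"] <- TRUE                  # 0.25
  mat[, "c#1"] <- TRUE                      # 1.0
  db <- as_transaction_db(mat)
  expect_identical(colnames(filter_small_intervals(db, 0.05)$mat),
                   c("b#1", "c#1"))
  expect_identical(filter_small_intervals(db, 0)$mat, db$mat)
  expect_identical(colnames(filter_small_intervals(db, 1)$mat), "c#1")
})

test_that("width-mode interval filtering uses the training range", {
  v <- matrix(c(0, 1, 9, 10,
                0, 4, 6, 10), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  x <- expression_matrix(v, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
  sch <- build_scheme(x, "ewib", n_bins = 4L)   # finite widths 2.5 = 25%
  dm <- apply_scheme(x, sch)
  db <- build_transactions(dm, "A")
  kept <- filter_small_intervals(db, 0.3, mode = "width", scheme = sch)
  iv <- intclass:::split_items(colnames(kept$mat))$interval
  expect_true(all(iv %in% c(1L, 5L)))   # only the infinite extremes survive
})

test_that("mine_mfi reproduces the worked lattice examples", {
  mat <- rbind(c(TRUE, TRUE, TRUE),
               c(TRUE, TRUE, FALSE),
               c(TRUE, FALSE, TRUE),
               c(FALSE, TRUE, TRUE))
  colnames(mat) <- c("a#1", "b#1", "c#1")
  res <- mine_mfi(as_transaction_db(mat), 0.5)
  got <- lapply(res$itemsets, identity)
  expect_setequal(got, list(c("a#1", "b#1"), c("a#1", "c#1"), c("b#1", "c#1")))
  expect_equal(res$supports, rep(0.5, 3))

  one <- matrix(TRUE, 1, 2, dimnames = list(NULL, c("a#1", "b#1")))
  expect_identical(mine_mfi(as_transaction_db(one), 1)$itemsets,
                   list(c("a#1", "b#1")))

  two <- rbind(c(TRUE, FALSE), c(FALSE, TRUE))
  colnames(two) <- c("a#1", "b#1")
  expect_identical(mine_mfi(as_transaction_db(two), 0.6)$itemsets, list())

  empty <- matrix(FALSE, 0, 0)
  expect_identical(mine_mfi(as_transaction_db(empty), 0.4)$itemsets, list())
})

test_that("mine_mfi is deterministic and canonically ordered", {
  set.seed(17)
  m <- random_db_matrix(12, 8)
  db <- as_transaction_db(m)
  r1 <- mine_mfi(db, 0.3)
  r2 <- mine_mfi(db, 0.3)
  expect_identical(r1, r2)
  sizes <- lengths(r1$itemsets)
  expect_true(all(diff(sizes) <= 0))       # size descending
})

test_that("mine_mfi matches brute force on 60 random databases", {
  set.seed(2024)
  for (i in 1:60) {
    n <- sample(2:12, 1L)
    p <- sample(2:10, 1L)
    dens <- runif(1, 0.25, 0.8)
    m <- random_db_matrix(n, p, dens)
    ms <- sample(seq(0.2, 0.9, 0.1), 1L)
    db <- as_transaction_db(m)
    got <- lapply(mine_mfi(db, ms)$itemsets,
                  function(k) sort(match(k, colnames(m))))
    want <- lapply(oracle_mfi(m, ms), sort)
    expect_setequal(got, want)
    # completeness: every frequent itemset lies inside some returned MFI
    for (fs in oracle_frequent(m, ms))
      expect_true(any(vapply(got, function(g) all(fs %in% g), logical(1L))))
  }
})
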