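test_that("a well-formed matrix/label pair parses with shape and classes intact", {
  cells <- matrix(sprintf("%.2f", 1:12), 3, 4,
                  dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:4)))
  labels <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
  fx <- write_matrix_fixture(cells, labels)
  x <- read_expression_matrix(fx$matrix, fx$labels)
  expect_identical(dim(x$values), c(3L, 4L))
  expect_identical(rownames(x$values), c("gA", "gB", "gC"))  # order-preserving
  expect_identical(colnames(x$values), paste0("s", 1:4))
  expect_identical(sort(unique(x$labels)), c("A", "B"))
  expect_equal(x$values["gA", "s2"], 4)
})

test_that("transpose flag accepts samples-in-rows files", {
  cells <- matrix(sprintf("%d", 1:12), 4, 3,
                  dimnames = list(paste0("s", 1:4), c("gA", "gB", "gC")))
  labels <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
  fx <- write_matrix_fixture(cells, labels)
  # header row now holds gene ids, first column sample ids
  x <- read_expression_matrix(fx$matrix, fx$labels, transpose = TRUE)
  expect_identical(rownames(x$values), c("gA", "gB", "gC"))
  expect_identical(colnames(x$values), paste0("s", 1:4))
})

test_that("GCT-like '#' preamble lines are skipped", {
  cells <- matrix(c("1", "2"), 1, 2, dimnames = list("g1", c("s1", "s2")))
  labels <- c(s1 = "A", s2 = "B")
  fx <- write_matrix_fixture(cells, labels)
  raw <- readLines(fx$matrix)
  writeLines(c("#1.2", "# 1 2", raw), fx$matrix)
  x <- read_expression_matrix(fx$matrix, fx$labels)
  expect_equal(unname(x$values["g1", ]), c(1, 2))
})

test_that("malformed cells, duplicate ids and label mismatches are rejected", {
  cells <- matrix(sprintf("%d", 1:4), 2, 2,
                  dimnames = list(c("gA", "gB"), c("s1", "s2")))
  labels <- c(s1 = "A", s2 = "B")
  bad <- cells; bad["gB", "s2"] <- "NA"
  fx <- write_matrix_fixture(bad, labels)
  err <- expect_error(read_expression_matrix(fx$matrix, fx$labels),
                      class = "ic_parse_error")
  expect_match(conditionMessage(err), "gB")
  expect_match(conditionMessage(err), "s2")

  dup <- cells; rownames(dup) <- c("gA", "gA")
  fx <- write_matrix_fixture(dup, labels)
  expect_error(read_expression_matrix(fx$matrix, fx$labels),
               class = "ic_validation_error")

  fx <- write_matrix_fixture(cells, labels[1L])   # s2 missing from labels
  expect_error(read_expression_matrix(fx$matrix, fx$labels),
               class = "ic_validation_error")
  fx <- write_matrix_fixture(cells, c(labels, s9 = "A"))  # extra label sample
  expect_error(read_expression_matrix(fx$matrix, fx$labels),
               class = "ic_validation_error")
  fx <- write_matrix_fixture(cells, c(s1 = "A", s2 = "A"))  # single class
  expect_error(read_expression_matrix(fx$matrix, fx$labels),
               class = "ic_validation_error")
})

test_that("matrix write/read round trip is exact", {
  set.seed(11)
  v <- matrix(rnorm(30) * 10^sample(-3:3, 30, TRUE), 5, 6,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  labels <- stats::setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  x <- expression_matrix(v, labels)
  mp <- tempfile(); lp <- tempfile()
  write_expression_matrix(x, mp, lp)
  y <- read_expression_matrix(mp, lp)
  expect_identical(y$values, x$values)
  expect_identical(y$labels, x$labels)
})

test_that("rule serialization mirrors the published line format", {
  r <- rule("HOXB13", -0.68, -0.09, "NonRecurrence")
  expect_identical(format(r), "HOXB13[-0.68,-0.09]\tNonRecurrence")
  p <- tempfile()
  write_rules(list(r), p, format = "plain")
  expect_identical(readLines(p), "HOXB13[-0.68,-0.09]\tNonRecurrence")
})

test_that("rule sets round-trip exactly, including infinities and metadata", {
  rules <- list(
    rule(c("IL17BR", "DOK2"), c(0.79, 2.29), c(0.98, 2.44), "NonRecurrence",
         support = 0.5, confidence = 0.9),
    rule(c("APS"), 0.18, Inf, "Recurrence", support = 1 / 3,
         confidence = 0.123456789012345))
  p <- tempfile()
  write_rules(rules, p)
  back <- read_rules(p)
  expect_equal(back, rules)
  expect_match(readLines(p)[2L], "APS\\[0.18,\\+inf\\]")
  # bitwise-identical second write
  p2 <- tempfile()
  write_rules(back, p2)
  expect_identical(readLines(p2), readLines(p))
})

test_that("empty rule set round-trips and bad rule lines name their line", {
  p <- tempfile()
  write_rules(list(), p)
  expect_identical(read_rules(p), list())
  writeLines(c("GENE[0,1]\tA", "garbage-without-tab"), p)
  err <- expect_error(read_rules(p), class = "ic_parse_error")
  expect_match(conditionMessage(err), "line 2")
})

test_that("rule constructor enforces the antecedent invariants", {
  expect_error(rule(character(), numeric(), numeric(), "A"),
               class = "ic_validation_error")
  expect_error(rule(c("g1", "g1"), c(0, 1), c(1, 2), "A"),
               class = "ic_validation_error")
  expect_error(rule("g1", 2, 1, "A"), class = "ic_validation_error")
  expect_error(rule("g1", 0, 1, "A", support = 1.5),
               class = "ic_validation_error")
})
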