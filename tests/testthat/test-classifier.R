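mk_rule <- function(genes, intervals, class) {
  list(genes = genes, intervals = intervals, class = class,
       support = 0.5, confidence = 0.9)
}

mk_ruleset <- function(rules, classes = c("A", "B"), class_n = c(A = 4L, B = 4L)) {
  intclass:::new_rule_set(rules, classes, class_n, 0.05)
}

test_that("rule match fraction is m / |antecedent|", {
  u <- c(g1 = 1L, g2 = 2L, g3 = 1L, g4 = 3L)
  r4 <- mk_rule(paste0("g", 1:4), c(1L, 2L, 1L, 3L), "A")
  expect_equal(rule_match_fraction(u, r4), 1)
  r_half <- mk_rule(paste0("g", 1:4), c(1L, 2L, 9L, 9L), "A")
  expect_equal(rule_match_fraction(u, r_half), 0.5)
  r_none <- mk_rule(c("g1", "g2"), c(9L, 9L), "A")
  expect_equal(rule_match_fraction(u, r_none), 0)
})

test_that("class scores average f over rules, with both variants", {
  u <- c(g1 = 1L, g2 = 1L)
  full <- mk_rule(c("g1", "g2"), c(1L, 1L), "A")   # f = 1
  half <- mk_rule(c("g1", "g2"), c(1L, 2L), "A")   # f = 0.5
  expect_equal(class_score(u, list(full, half), "f1"), 0.75)
  expect_equal(class_score(u, list(full, half), "f2"), 0.625)
  expect_equal(class_score(u, list(), "f1"), 0)
})

test_that("f variants are bounded, f2 <= f1, and scores are rule-order invariant", {
  set.seed(6)
  for (i in 1:20) {
    u <- stats::setNames(sample(1:3, 6, TRUE), paste0("g", 1:6))
    rules <- lapply(1:5, function(j) {
      k <- sample(1:4, 1L)
      g <- sample(paste0("g", 1:6), k)
      mk_rule(g, sample(1:3, k, TRUE), "A")
    })
    f1 <- vapply(rules, rule_match_fraction, numeric(1L), sample = u)
    expect_true(all(f1 >= 0 & f1 <= 1))
    s1 <- class_score(u, rules, "f1")
    s2 <- class_score(u, rules, "f2")
    expect_lte(s2, s1 + 1e-15)
    expect_true(s1 >= 0 && s1 <= 1)
    perm <- sample(seq_along(rules))
    expect_equal(class_score(u, rules[perm], "f1"), s1)
  }
})

test_that("adding a rule obeys the exact renormalization identity", {
  set.seed(61)
  for (i in 1:20) {
    u <- stats::setNames(sample(1:3, 5, TRUE), paste0("g", 1:5))
    rules <- lapply(seq_len(sample(1:6, 1L)), function(j) {
      k <- sample(1:3, 1L)
      g <- sample(paste0("g", 1:5), k)
      mk_rule(g, sample(1:3, k, TRUE), "A")
    })
    extra <- mk_rule("g1", sample(1:3, 1L), "A")
    s_old <- class_score(u, rules, "f1")
    f <- rule_match_fraction(u, extra)
    s_new <- class_score(u, c(rules, list(extra)), "f1")
    expect_equal(s_new, (length(rules) * s_old + f) / (length(rules) + 1L),
                 tolerance = 1e-15)
  }
})

test_that("prediction takes the maximizing class with the deterministic tie rule", {
  u <- c(g1 = 1L, g2 = 1L)
  rs <- mk_ruleset(list(mk_rule(c("g1", "g2"), c(1L, 1L), "A"),
                        mk_rule(c("g1", "g2"), c(2L, 2L), "B")))
  res <- predict_sample(u, rs)
  expect_identical(res$predicted_class, "A")
  expect_equal(res$margin, 1)
  expect_equal(unname(res$scores), c(1, 0))
  # exact tie between equally sized classes -> lexicographically first
  tie <- mk_ruleset(list(mk_rule("g1", 1L, "A"), mk_rule("g1", 1L, "B")))
  expect_identical(predict_sample(u, tie)$predicted_class, "A")
  # tie broken toward the larger training class first
  tie2 <- mk_ruleset(list(mk_rule("g1", 1L, "A"), mk_rule("g1", 1L, "B")),
                     class_n = c(A = 3L, B = 5L))
  expect_identical(predict_sample(u, tie2)$predicted_class, "B")
})

test_that("planted-signature samples go to their planted class", {
  ds <- synthesize_dataset(n_per_class = 12L, n_signature = 6L, n_noise = 30L,
                           effect_size = 3, seed = 9)
  m <- train_model(ds$x)
  pred <- predict(m, ds$x)
  expect_equal(mean(pred$predicted == ds$x$labels), 1)
})

test_that("one-versus-all with K = 2 reproduces the binary decision", {
  ds <- synthesize_dataset(n_per_class = 10L, n_signature = 5L, n_noise = 20L,
                           effect_size = 3, seed = 10)
  bin <- train_model(ds$x)
  ova <- train_ova(ds$x)
  pb <- predict(bin, ds$x)
  po <- predict(ova, ds$x)
  expect_identical(po$predicted, pb$predicted)
})

test_that("four disjoint shift classes self-classify perfectly under OVA", {
  ds <- synthesize_dataset(n_per_class = 8L, n_classes = 4L, n_signature = 6L,
                           n_noise = 20L, effect_size = 4, seed = 12)
  ova <- train_ova(ds$x)
  pred <- predict(ova, ds$x)
  expect_equal(mean(pred$predicted == ds$x$labels), 1)
})
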