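#' Fraction of a rule's antecedent matched by a discretized sample
#'
#' With `m` the number of antecedent items whose (gene, interval) pair the
#' sample carries, returns `m / |antecedent|`.
#'
#' @param sample Named integer vector: interval index per gene (a column of
#'   a `disc_matrix`).
#' @param rule A rule as stored in a `rule_set` (fields `genes`,
#'   `intervals`).
#' @return Fraction in `[0, 1]`.
#' @export
rule_match_fraction <- function(sample, rule) {
  m <- sum(sample[rule$genes] == rule$intervals, na.rm = TRUE)
  m / length(rule$genes)
}

#' Rule-satisfaction score of a sample for one class
#'
#' `S(u, c) = (1 / |R_c|) * sum_r f(u, r)` over the class's rules, where
#' `f1(u, r) = m / |antecedent|` is the linear match fraction and
#' `f2(u, r) = (m / |antecedent|)^2` rewards near-complete satisfaction.
#' Both variants are reconstructions of the two satisfaction functions the
#' method family uses; they agree on fully matched and fully unmatched
#' rules and `f2 <= f1` pointwise. An empty rule list scores 0.
#'
#' @param sample Named integer vector of interval indices per gene.
#' @param rules_c List of rules of a single class.
#' @param variant `"f1"` (default) or `"f2"`.
#' @return Score in `[0, 1]`.
#' @export
class_score <- function(sample, rules_c, variant = c("f1", "f2")) {
  variant <- match.arg(variant)
  if (!length(rules_c)) return(0)
  f <- vapply(rules_c, rule_match_fraction, numeric(1L), sample = sample)
  if (variant == "f2") f <- f^2
  mean(f)
}

# Match-fraction matrix: rules x samples.
rule_fracs <- function(rules, cells, variant) {
  n <- ncol(cells)
  Fm <- matrix(0, length(rules), n)
  for (j in seq_along(rules)) {
    r <- rules[[j]]
    sub <- cells[r$genes, , drop = FALSE] == r$intervals
    Fm[j, ] <- colSums(sub) / length(r$genes)
  }
  if (variant == "f2") Fm <- Fm^2
  Fm
}

# Class-score matrix (classes x samples) from a fraction matrix.
score_matrix_from_fracs <- function(Fm, rule_classes, classes) {
  Sm <- matrix(0, length(classes), ncol(Fm),
               dimnames = list(classes, colnames(Fm)))
  for (k in seq_along(classes)) {
    idx <- which(rule_classes == classes[k])
    if (length(idx))
      Sm[k, ] <- colMeans(Fm[idx, , drop = FALSE])
  }
  Sm
}

# Deterministic argmax with the package tie rule: larger training class
# first, then lexicographic label order (classes are sorted already).
predict_from_scores <- function(Sm, classes, class_n) {
  pref <- order(-class_n, classes, method = "radix")
  Sp <- Sm[pref, , drop = FALSE]
  classes[pref[max.col(t(Sp), ties.method = "first")]]
}

# Scores + prediction + margin for a cell matrix under a rule set.
classify_cells <- function(rules, cells, variant) {
  Fm <- rule_fracs(rules$rules, cells, variant)
  Sm <- score_matrix_from_fracs(
    Fm, vapply(rules$rules, `[[`, character(1L), "class"), rules$classes)
  pred <- predict_from_scores(Sm, rules$classes, rules$class_n)
  margin <- apply(Sm, 2L, function(s) {
    ss <- sort(s, decreasing = TRUE)
    if (length(ss) > 1L) ss[1L] - ss[2L] else ss[1L]
  })
  list(scores = Sm, predicted = pred, margin = margin)
}

#' Score and classify one discretized sample
#'
#' Computes `S(u, c)` for every class of the rule set and assigns the
#' maximizing class; ties are broken toward the class with more training
#' samples, then lexicographic label order.
#'
#' @param sample Named integer vector of interval indices per gene.
#' @param rules A `rule_set`.
#' @param variant `"f1"` or `"f2"`.
#' @return A list of class `class_score_result`: `scores` (named numeric per
#'   class), `predicted_class`, `margin` (best minus second-best score).
#' @export
predict_sample <- function(sample, rules, variant = c("f1", "f2")) {
  variant <- match.arg(variant)
  cells <- matrix(sample, ncol = 1L, dimnames = list(names(sample), "u"))
  res <- classify_cells(rules, cells, variant)
  structure(list(scores = res$scores[, 1L], predicted_class = res$predicted,
                 margin = res$margin[[1L]]),
            class = "class_score_result")
}
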