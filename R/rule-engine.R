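#' Generate class-association rules from per-class maximal itemsets
#'
#' Each maximal frequent itemset of class `c` becomes one candidate rule
#' with the itemset as antecedent and `c` as consequent. Support is the
#' class-local support of the antecedent; confidence is the number of
#' training samples of class `c` containing the antecedent divided by the
#' number of training samples of any class containing it — i.e. the
#' empirical P(class | antecedent). Candidates below `min_confidence`, or
#' contained in no training sample at all, are dropped.
#'
#' @param mfis_by_class Named list (class label -> `mfi_set`) mined from the
#'   same discretized training matrix.
#' @param dm The training `disc_matrix`.
#' @param min_confidence Minimum confidence in `[0, 1]` (default 0.05).
#' @return An object of class `rule_set`: `rules` (list; each rule has
#'   `genes`, `intervals`, `class`, `support`, `confidence`), `classes`,
#'   `class_n` (training samples per class), `min_confidence`.
#' @export
rules_from_mfis <- function(mfis_by_class, dm, min_confidence = 0.05) {
  if (min_confidence < 0 || min_confidence > 1)
    ic_validation("'min_confidence' must lie in [0, 1]")
  classes <- sort(names(mfis_by_class))
  class_n <- vapply(classes, function(cl) sum(dm$labels == cl), integer(1L))
  rules <- list()
  for (cl in classes) {
    for (set in mfis_by_class[[cl]]$itemsets) {
      it <- split_items(set)
      contained <- rule_containment(dm$cells, it$gene, it$interval)
      n_all <- sum(contained)
      if (n_all == 0L) next
      n_c <- sum(contained & dm$labels == cl)
      conf <- n_c / n_all
      if (conf < min_confidence) next
      rules[[length(rules) + 1L]] <-
        list(genes = it$gene, intervals = it$interval, class = cl,
             support = n_c / class_n[[cl]], confidence = conf)
    }
  }
  new_rule_set(rules, classes, class_n, min_confidence)
}

new_rule_set <- function(rules, classes, class_n, min_confidence) {
  structure(list(rules = rules, classes = classes, class_n = class_n,
                 min_confidence = min_confidence),
            class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  per <- table(factor(vapply(x$rules, `[[`, character(1L), "class"),
                      levels = x$classes))
  cat(sprintf("<rule_set> %d rules (min confidence %g): %s\n",
              length(x$rules), x$min_confidence,
              paste(sprintf("%s: %d", names(per), per), collapse = ", ")))
  invisible(x)
}

# Logical vector over samples: does the sample contain the whole antecedent?
rule_containment <- function(cells, genes, intervals) {
  sub <- cells[genes, , drop = FALSE] == intervals
  colSums(sub) == length(genes)
}

rule_signature <- function(r) {
  paste(sort(paste0(r$genes, "#", r$intervals)), collapse = "\r")
}

# Canonical processing order: class label, antecedent size descending,
# lexicographic signature.
canonical_rule_order <- function(rules) {
  cls <- vapply(rules, `[[`, character(1L), "class")
  sz <- lengths(lapply(rules, `[[`, "genes"))
  sig <- vapply(rules, rule_signature, character(1L))
  order(cls, -sz, sig, method = "radix")
}

#' Greedy leave-one-gene-out pruning of rule antecedents
#'
#' For each rule (in canonical order), items are visited in lexicographic
#' gene order; an item is removed permanently when removing it does not
#' decrease the training-set accuracy of the whole rule set, keeps the
#' rule's confidence at or above the set's minimum, and does not duplicate
#' another antecedent of the same class. A rule is never reduced below one
#' item. Passes are repeated until a fixed point, so the operation is
#' idempotent and the final training accuracy is at least the initial one.
#'
#' @param rules A `rule_set` from [rules_from_mfis()].
#' @param dm The training `disc_matrix` the rules were generated from.
#' @param variant Scoring variant used by the accuracy criterion, `"f1"` or
#'   `"f2"` (see [class_score()]).
#' @param max_passes Safety bound on fixed-point iterations.
#' @return The pruned `rule_set` (supports and confidences recomputed).
#' @export
loo_prune_rules <- function(rules, dm, variant = c("f1", "f2"),
                            max_passes = 25L) {
  variant <- match.arg(variant)
  if (!length(rules$rules)) return(rules)
  rl <- rules$rules[canonical_rule_order(rules$rules)]
  classes <- rules$classes
  class_n <- rules$class_n
  cells <- dm$cells
  labs <- dm$labels
  Fm <- rule_fracs(rl, cells, variant)
  Sm <- score_matrix_from_fracs(Fm, vapply(rl, `[[`, character(1L), "class"),
                                classes)
  acc <- mean(predict_from_scores(Sm, classes, class_n) == labs)
  rule_cls <- vapply(rl, `[[`, character(1L), "class")
  cls_rows <- lapply(classes, function(cl) which(rule_cls == cl))
  names(cls_rows) <- classes
  sigs <- vapply(rl, rule_signature, character(1L))
  for (pass in seq_len(max_passes)) {
    changed <- FALSE
    for (j in seq_along(rl)) {
      for (g in sort(rl[[j]]$genes)) {
        if (length(rl[[j]]$genes) <= 1L) break
        r <- rl[[j]]
        if (!g %in% r$genes) next
        keep <- r$genes != g
        cand_genes <- r$genes[keep]
        cand_iv <- r$intervals[keep]
        sig <- paste(sort(paste0(cand_genes, "#", cand_iv)), collapse = "\r")
        if (any(sigs[-j] == sig & rule_cls[-j] == r$class)) next
        contained <- rule_containment(cells, cand_genes, cand_iv)
        n_all <- sum(contained)
        if (n_all == 0L) next
        n_c <- sum(contained & labs == r$class)
        conf <- n_c / n_all
        if (conf < rules$min_confidence) next
        newrow <- colSums(cells[cand_genes, , drop = FALSE] == cand_iv) /
          length(cand_genes)
        if (variant == "f2") newrow <- newrow^2
        # recompute the class's score row exactly (no incremental drift, so
        # repeated pruning reproduces bit-identical comparisons)
        ci <- match(r$class, classes)
        rows <- cls_rows[[r$class]]
        tmp <- Fm[rows, , drop = FALSE]
        tmp[match(j, rows), ] <- newrow
        Sm_new <- Sm
        Sm_new[ci, ] <- colMeans(tmp)
        acc_new <- mean(predict_from_scores(Sm_new, classes, class_n) == labs)
        if (acc_new >= acc) {
          rl[[j]] <- list(genes = cand_genes, intervals = cand_iv,
                          class = r$class,
                          support = n_c / class_n[[r$class]],
                          confidence = conf)
          Fm[j, ] <- newrow
          Sm <- Sm_new
          acc <- acc_new
          sigs[j] <- sig
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  # canonical order of the *pruned* antecedents, so the fixed point is
  # reproduced exactly by a repeated call
  new_rule_set(rl[canonical_rule_order(rl)], classes, class_n,
               rules$min_confidence)
}
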