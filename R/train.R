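#' Pipeline hyperparameter configuration
#'
#' Collects every tunable of the training pipeline with its default.
#' Unknown keys are rejected; fraction-valued parameters are checked to lie
#' in `[0, 1]`.
#'
#' @param alpha Gene-filter significance cutoff (default 0.05).
#' @param filter Screening statistic: `"t"` (Welch t-test, default), `"ks"`
#'   (Kolmogorov-Smirnov) or `"none"` (keep every gene).
#' @param adjust Multiple-testing adjustment for the filter: `"none"`
#'   (default) or `"bh"`.
#' @param discretizer `"id3"` (default), `"ewib"`, `"none"` or `"ternary"`.
#' @param bins EWIB bin count (default 5).
#' @param min_leaf ID3 minimum samples per side of a cut (default 2).
#' @param ternary_z Ternary half-width in standard deviations (default 1).
#' @param minsup Minimum itemset support (default 0.4).
#' @param min_interval_size Minimal-interval-size threshold (default 0.05).
#' @param interval_size_mode `"coverage"` (default) or `"width"`.
#' @param min_confidence Minimum rule confidence (default 0.05).
#' @param score Satisfaction variant, `"f1"` (default) or `"f2"`.
#' @param prune Run leave-one-gene-out rule pruning (default `TRUE`).
#' @param seed Integer recorded in model metadata (the pipeline itself is
#'   deterministic; the seed matters for synthetic-data workflows).
#' @return A list of class `run_config`.
#' @export
run_config <- function(alpha = 0.05, filter = "t", adjust = "none",
                       discretizer = "id3", bins = 5L, min_leaf = 2L,
                       ternary_z = 1, minsup = 0.4, min_interval_size = 0.05,
                       interval_size_mode = "coverage", min_confidence = 0.05,
                       score = "f1", prune = TRUE, seed = 0L) {
  cfg <- list(alpha = alpha, filter = filter, adjust = adjust,
              discretizer = discretizer, bins = as.integer(bins),
              min_leaf = as.integer(min_leaf), ternary_z = ternary_z,
              minsup = minsup, min_interval_size = min_interval_size,
              interval_size_mode = interval_size_mode,
              min_confidence = min_confidence, score = score,
              prune = isTRUE(prune), seed = as.integer(seed))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  allowed <- names(formals(run_config))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) ic_validation("unknown config key '%s'", unknown[1L])
  for (k in setdiff(allowed, names(cfg)))
    cfg[[k]] <- formals(run_config)[[k]]
  cfg <- cfg[allowed]
  chk <- function(val, name, lo, hi)
    if (!is.numeric(val) || length(val) != 1L || is.na(val) || val < lo || val > hi)
      ic_validation("config '%s' must lie in [%g, %g]", name, lo, hi)
  chk(cfg$alpha, "alpha", 1e-12, 1)
  chk(cfg$minsup, "minsup", 1e-12, 1)
  chk(cfg$min_interval_size, "min_interval_size", 0, 1)
  chk(cfg$min_confidence, "min_confidence", 0, 1)
  match_or_die <- function(val, name, choices) {
    if (!val %in% choices)
      ic_validation("config '%s' must be one of: %s", name,
                    paste(choices, collapse = ", "))
    val
  }
  cfg$filter <- match_or_die(cfg$filter, "filter", c("t", "ks", "none"))
  cfg$adjust <- match_or_die(cfg$adjust, "adjust", c("none", "bh"))
  cfg$discretizer <- match_or_die(cfg$discretizer, "discretizer",
                                  c("id3", "ewib", "none", "ternary"))
  cfg$interval_size_mode <- match_or_die(cfg$interval_size_mode,
                                         "interval_size_mode",
                                         c("coverage", "width"))
  cfg$score <- match_or_die(cfg$score, "score", c("f1", "f2"))
  structure(cfg, class = "run_config")
}

#' Train a binary interval-rule classifier
#'
#' Runs the full pipeline on a two-class expression matrix: gene screening,
#' per-gene discretization, minimal-interval-size filtering, per-class
#' maximal frequent itemset mining, rule generation, and (optionally)
#' greedy rule pruning.
#'
#' @param x An [expression_matrix()] with exactly two classes.
#' @param config A [run_config()] (or arguments via `...`).
#' @param ... Convenience overrides forwarded to [run_config()] when
#'   `config` is missing.
#' @param verbose Emit per-stage counts via [message()].
#' @return An object of class `interval_classifier`: `config`, `classes`,
#'   `class_n`, `filter` (the `filter_result`), `scheme`, `rules`.
#' @export
train_model <- function(x, config = NULL, ..., verbose = FALSE) {
  cfg <- if (is.null(config)) run_config(...) else validate_config(config)
  classes <- class_labels(x)
  if (length(classes) != 2L)
    ic_validation("train_model needs exactly 2 classes (got %d); use train_ova",
                  length(classes))
  filt <- switch(cfg$filter,
                 t = t_filter(x, classes[1L], classes[2L], cfg$alpha, cfg$adjust),
                 ks = ks_filter(x, classes[1L], classes[2L], cfg$alpha, cfg$adjust),
                 none = structure(list(kept_gene_ids = rownames(x$values),
                                       p_values = NULL, alpha = 1),
                                  class = "filter_result"))
  if (!length(filt$kept_gene_ids))
    ic_validation("gene filter kept no genes at alpha = %g", cfg$alpha)
  if (verbose)
    message(sprintf("[filter] kept %d / %d genes",
                    length(filt$kept_gene_ids), nrow(x$values)))
  xk <- subset_matrix(x, genes = filt$kept_gene_ids)
  scheme <- build_scheme(xk, cfg$discretizer, min_leaf = cfg$min_leaf,
                         n_bins = cfg$bins, z = cfg$ternary_z)
  dm <- apply_scheme(xk, scheme)
  if (verbose)
    message(sprintf("[discretize] %s; mean %.1f intervals/gene", cfg$discretizer,
                    mean(lengths(scheme$cuts) + 1L)))
  mfis <- list()
  for (cl in classes) {
    db <- build_transactions(dm, cl)
    db <- filter_small_intervals(db, cfg$min_interval_size,
                                 cfg$interval_size_mode, scheme)
    mfis[[cl]] <- mine_mfi(db, cfg$minsup)
    if (verbose)
      message(sprintf("[mine] class %s: %d items, %d maximal itemsets",
                      cl, ncol(db$mat), length(mfis[[cl]]$itemsets)))
  }
  rules <- rules_from_mfis(mfis, dm, cfg$min_confidence)
  if (verbose) message(sprintf("[rules] %d rules", length(rules$rules)))
  if (cfg$prune) {
    rules <- loo_prune_rules(rules, dm, cfg$score)
    if (verbose) message(sprintf("[prune] %d rules after pruning",
                                 length(rules$rules)))
  }
  structure(list(config = cfg, classes = classes,
                 class_n = rules$class_n, filter = filt,
                 scheme = scheme, rules = rules),
            class = "interval_classifier")
}

#' @export
print.interval_classifier <- function(x, ...) {
  cat(sprintf("<interval_classifier> classes %s; %d genes; %d rules (%s, score %s)\n",
              paste(x$classes, collapse = " / "), length(x$scheme$cuts),
              length(x$rules$rules), x$config$discretizer, x$config$score))
  invisible(x)
}

#' Classify new samples with a trained model
#'
#' @param object An `interval_classifier` from [train_model()].
#' @param newdata An `expr_matrix` or a plain numeric genes-by-samples
#'   matrix containing at least the model's genes.
#' @param ... Unused.
#' @return A data frame with one row per sample: `sample`, `predicted`,
#'   one score column per class, `margin`, and for binary models
#'   `statistic` (score of the lexicographically last class minus the
#'   first, the ROC decision statistic).
#' @export
predict.interval_classifier <- function(object, newdata, ...) {
  values <- if (inherits(newdata, "expr_matrix")) newdata$values else newdata
  if (!is.matrix(values)) ic_validation("'newdata' must be a matrix")
  cells <- discretize_values(values, object$scheme)
  res <- classify_cells(object$rules, cells, object$config$score)
  out <- data.frame(sample = colnames(values), predicted = res$predicted,
                    stringsAsFactors = FALSE)
  for (k in seq_along(object$classes))
    out[[paste0("score_", object$classes[k])]] <- res$scores[k, ]
  out$margin <- res$margin
  if (length(object$classes) == 2L)
    out$statistic <- res$scores[2L, ] - res$scores[1L, ]
  rownames(out) <- NULL
  out
}

#' One-versus-all multi-class training
#'
#' Trains one binary model per class against the union of the remaining
#' classes (label `".rest"`), each with its own gene filtering,
#' discretization, mining and pruning.
#'
#' @param x An [expression_matrix()] with `K >= 2` classes.
#' @inheritParams train_model
#' @return An object of class `ova_classifier`: `classes`, `class_n`,
#'   `models` (one `interval_classifier` per class), `config`.
#' @export
train_ova <- function(x, config = NULL, ..., verbose = FALSE) {
  cfg <- if (is.null(config)) run_config(...) else validate_config(config)
  classes <- class_labels(x)
  if (".rest" %in% classes)
    ic_validation("class label '.rest' is reserved by the one-versus-all wrapper")
  models <- lapply(classes, function(cl) {
    labs <- ifelse(x$labels == cl, cl, ".rest")
    names(labs) <- names(x$labels)
    xb <- expression_matrix(x$values, labs)
    train_model(xb, cfg, verbose = verbose)
  })
  names(models) <- classes
  class_n <- vapply(classes, function(cl) sum(x$labels == cl), integer(1L))
  structure(list(classes = classes, class_n = class_n, models = models,
                 config = cfg),
            class = "ova_classifier")
}

#' @export
print.ova_classifier <- function(x, ...) {
  cat(sprintf("<ova_classifier> %d one-vs-rest models: %s\n",
              length(x$models), paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' @rdname train_ova
#' @param object An `ova_classifier`.
#' @param newdata Matrix or `expr_matrix` of samples to classify.
#' @export
predict.ova_classifier <- function(object, newdata, ...) {
  values <- if (inherits(newdata, "expr_matrix")) newdata$values else newdata
  margins <- vapply(object$classes, function(cl) {
    m <- object$models[[cl]]
    cells <- discretize_values(values, m$scheme)
    res <- classify_cells(m$rules, cells, m$config$score)
    res$scores[cl, ] - res$scores[".rest", ]
  }, numeric(ncol(values)))
  margins <- matrix(margins, ncol = length(object$classes),
                    dimnames = list(colnames(values), object$classes))
  pred <- predict_from_scores(t(margins), object$classes, object$class_n)
  out <- data.frame(sample = colnames(values), predicted = pred,
                    stringsAsFactors = FALSE)
  for (cl in object$classes) out[[paste0("margin_", cl)]] <- margins[, cl]
  rownames(out) <- NULL
  out
}
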