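#' ROC curve by threshold sweep
#'
#' Sweeps the unique decision-statistic values as thresholds (predict
#' positive when `statistic >= threshold`), so tied statistics move
#' together and produce diagonal segments. The curve starts at (0, 0) and
#' ends at (1, 1) and is monotone non-decreasing in both coordinates.
#'
#' @param statistic Numeric decision statistic, larger meaning more
#'   positive.
#' @param truth Class labels aligned with `statistic`.
#' @param positive The positive class label.
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(statistic, truth, positive) {
  pos <- truth == positive
  if (!any(pos) || all(pos))
    ic_validation("ROC needs both positive and negative samples")
  thr <- sort(unique(statistic), decreasing = TRUE)
  tpr <- vapply(thr, function(t0) mean(statistic[pos] >= t0), numeric(1L))
  fpr <- vapply(thr, function(t0) mean(statistic[!pos] >= t0), numeric(1L))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Trapezoidal area under a ROC curve
#' @param roc Data frame from [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (roc$tpr[-1L] + roc$tpr[-nrow(roc)]) / 2)
}

#' Leave-one-out cross-validation of the full pipeline
#'
#' For each sample the entire pipeline — gene filter, discretization,
#' interval filtering, mining, rule generation and pruning — is refit on
#' the remaining `n - 1` samples (so the held-out sample never influences
#' any learned quantity) and the held-out sample is classified. For binary
#' problems a ROC curve and trapezoidal AUC over the per-sample decision
#' statistics are reported; `K > 2` classes are handled through the
#' one-versus-all wrapper.
#'
#' @param x An [expression_matrix()]; every class needs `>= 3` samples so
#'   each fold keeps `>= 2` per class for the gene filter.
#' @param config A [run_config()] (or overrides via `...`).
#' @param ... Forwarded to [run_config()] when `config` is missing.
#' @param positive Positive class for the ROC convention; default the
#'   lexicographically last label. Binary problems only.
#' @param verbose Report fold progress.
#' @return An object of class `evaluation_report`: `samples` (data frame
#'   with `sample`, `truth`, `predicted`, `statistic`), `accuracy`,
#'   `positive`, `roc`, `auc` (the last three `NULL` for `K > 2`),
#'   `config`.
#' @export
loocv <- function(x, config = NULL, ..., positive = NULL, verbose = FALSE) {
  cfg <- if (is.null(config)) run_config(...) else validate_config(config)
  counts <- table(x$labels)
  if (any(counts < 3L))
    ic_validation("LOOCV needs >= 3 samples per class (class '%s' has %d)",
                  names(counts)[which.min(counts)], min(counts))
  classes <- class_labels(x)
  binary <- length(classes) == 2L
  if (binary && is.null(positive)) positive <- classes[length(classes)]
  sids <- colnames(x$values)
  n <- length(sids)
  pred <- character(n)
  stat <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    xtr <- subset_matrix(x, samples = sids[-i])
    newv <- x$values[, i, drop = FALSE]
    if (binary) {
      model <- train_model(xtr, cfg)
      p <- predict(model, newv)
      pred[i] <- p$predicted
      stat[i] <- p[[paste0("score_", positive)]] -
        p[[paste0("score_", setdiff(classes, positive))]]
    } else {
      model <- train_ova(xtr, cfg)
      pred[i] <- predict(model, newv)$predicted
    }
    if (verbose && i %% 10L == 0L)
      message(sprintf("[loocv] %d / %d folds", i, n))
  }
  samples <- data.frame(sample = sids, truth = unname(x$labels),
                        predicted = pred, statistic = stat,
                        stringsAsFactors = FALSE)
  roc <- auc <- NULL
  if (binary) {
    roc <- roc_curve(stat, samples$truth, positive)
    auc <- auc_trapezoid(roc)
  }
  structure(list(samples = samples, accuracy = mean(pred == samples$truth),
                 positive = positive, roc = roc, auc = auc, config = cfg),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> LOOCV accuracy %.3f over %d samples%s\n",
              x$accuracy, nrow(x$samples),
              if (!is.null(x$auc)) sprintf("; AUC %.3f (positive = %s)",
                                           x$auc, x$positive) else ""))
  invisible(x)
}

#' Paired LOOCV comparison against a baseline discretizer
#'
#' Runs [loocv()] under the primary configuration and once more with only
#' the discretizer swapped (the interval-superiority experiment: the
#' coarse ternary up/normal/down baseline against learned intervals).
#'
#' @param x An [expression_matrix()].
#' @param config The primary [run_config()].
#' @param baseline_discretizer Discretizer for the baseline arm (default
#'   `"ternary"`).
#' @param ... Forwarded to [loocv()] (e.g. `verbose`).
#' @return A list with `primary` and `baseline` evaluation reports and
#'   `accuracies` (named numeric of length 2).
#' @export
compare_to_baseline <- function(x, config = NULL,
                                baseline_discretizer = "ternary", ...) {
  cfg <- if (is.null(config)) run_config() else validate_config(config)
  cfg_b <- cfg
  cfg_b$discretizer <- baseline_discretizer
  cfg_b <- validate_config(cfg_b)
  primary <- loocv(x, cfg, ...)
  baseline <- loocv(x, cfg_b, ...)
  list(primary = primary, baseline = baseline,
       accuracies = c(primary = primary$accuracy,
                      baseline = baseline$accuracy))
}
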