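#' Per-gene Welch two-sample t statistics and p-values
#'
#' Vectorized over genes: unequal-variance t with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value. Degenerate genes follow the
#' screening convention: both groups zero-variance with equal means gives
#' p = 1 (no evidence of separation), zero-variance with unequal means gives
#' p = 0 (perfect separation).
#'
#' @param values Numeric matrix, genes x samples.
#' @param idx_a,idx_b Column indices (or names) of the two groups, each of
#'   size >= 2.
#' @return A list with numeric vectors `t`, `df`, `p` (one entry per gene).
#' @export
welch_t <- function(values, idx_a, idx_b) {
  xa <- values[, idx_a, drop = FALSE]
  xb <- values[, idx_b, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  if (na < 2L || nb < 2L)
    ic_validation("Welch t-test needs >= 2 samples per class (got %d and %d)", na, nb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1L)
  vb <- rowSums((xb - mb)^2) / (nb - 1L)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  p <- 2 * pt(-abs(tt), df)
  deg <- se2 == 0
  if (any(deg)) {
    p[deg] <- ifelse(ma[deg] == mb[deg], 1, 0)
    tt[deg] <- ifelse(ma[deg] == mb[deg], 0, Inf * sign(ma[deg] - mb[deg]))
    df[deg] <- NA_real_
  }
  list(t = tt, df = df, p = stats::setNames(p, rownames(values)))
}

#' Filter genes by between-class significance
#'
#' Removes genes without significant between-class variability before
#' discretization. `t_filter()` uses the per-gene Welch t-test (the default
#' screening statistic); `ks_filter()` uses the two-sample
#' Kolmogorov-Smirnov test, which also detects mean-matched distributional
#' differences (e.g. variance or band structure) that a location test cannot
#' see. The screening step is deliberately pluggable.
#'
#' @param x An [expression_matrix()].
#' @param class_a,class_b The two class labels to contrast.
#' @param alpha Significance cutoff in `(0, 1]`; genes with `p <= alpha` are
#'   kept. Default 0.05.
#' @param adjust `"none"` (default, no multiple-testing correction) or
#'   `"bh"` for Benjamini-Hochberg adjustment of the p-values before the
#'   cutoff is applied.
#' @return A list of class `filter_result`: `kept_gene_ids` (in original
#'   matrix order), `p_values` (named, possibly adjusted), `alpha`.
#' @export
t_filter <- function(x, class_a, class_b, alpha = 0.05,
                     adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  idx <- filter_groups(x, class_a, class_b)
  p <- welch_t(x$values, idx$a, idx$b)$p
  finish_filter(p, alpha, adjust)
}

#' @rdname t_filter
#' @export
ks_filter <- function(x, class_a, class_b, alpha = 0.05,
                      adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  idx <- filter_groups(x, class_a, class_b)
  p <- apply(x$values, 1L, function(v) {
    suppressWarnings(stats::ks.test(v[idx$a], v[idx$b], exact = FALSE)$p.value)
  })
  finish_filter(stats::setNames(p, rownames(x$values)), alpha, adjust)
}

filter_groups <- function(x, class_a, class_b) {
  for (cl in c(class_a, class_b))
    if (!cl %in% x$labels) ic_validation("unknown class label '%s'", cl)
  a <- which(x$labels == class_a)
  b <- which(x$labels == class_b)
  if (length(a) < 2L || length(b) < 2L)
    ic_validation("each class needs >= 2 samples for gene filtering ('%s': %d, '%s': %d)",
                  class_a, length(a), class_b, length(b))
  list(a = a, b = b)
}

finish_filter <- function(p, alpha, adjust) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    ic_validation("'alpha' must lie in (0, 1]")
  if (adjust == "bh") p <- stats::setNames(p.adjust(p, "BH"), names(p))
  structure(list(kept_gene_ids = names(p)[p <= alpha],
                 p_values = p, alpha = alpha),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result> kept %d / %d genes at alpha = %g\n",
              length(x$kept_gene_ids), length(x$p_values), x$alpha))
  invisible(x)
}
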