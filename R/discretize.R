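#' Supervised entropy-based (ID3) cut points for one gene
#'
#' Recursive top-down splitting of a gene's expression values driven by the
#' class labels. Candidate cuts are midpoints between consecutive distinct
#' sorted values whose adjacent samples carry differing class labels
#' (boundary points); at each node the cut maximizing the information gain
#' of the class label is chosen (ties broken toward the smallest cut) and
#' both sides are split recursively. A node stops when it is class-pure,
#' has fewer than `2 * min_leaf` samples, or no candidate cut has strictly
#' positive gain; candidate cuts must leave at least `min_leaf` samples on
#' each side.
#'
#' @param values Numeric vector of expression values (one per sample).
#' @param labels Class label vector aligned with `values`.
#' @param min_leaf Minimum samples per side of any cut (default 2, which
#'   avoids one-sample intervals that the minimal-interval-size filter would
#'   discard anyway).
#' @return Sorted numeric vector of cut points (possibly empty).
#' @export
discretize_gene_id3 <- function(values, labels, min_leaf = 2L) {
  check_gene_vector(values)
  if (length(labels) != length(values))
    ic_validation("'labels' must align with 'values'")
  if (min_leaf < 1L) ic_validation("'min_leaf' must be >= 1")
  sort(id3_recurse(values, as.character(labels), as.integer(min_leaf))$cut)
}

# Internal: recursion that also records the information gain realized at
# each emitted cut (used by the property tests).
id3_recurse <- function(values, labels, min_leaf) {
  o <- order(values)
  v <- values[o]; labs <- labels[o]
  n <- length(v)
  empty <- data.frame(cut = numeric(), gain = numeric(), n_node = integer())
  if (n < 2L * min_leaf || length(unique(labs)) < 2L) return(empty)
  pos <- id3_cut_candidates(v, labs, min_leaf)
  if (!length(pos)) return(empty)
  gains <- id3_gains(v, labs, pos)
  best <- which.max(gains)                       # ties -> smallest cut (pos ascending)
  if (gains[best] <= 1e-12) return(empty)
  cut <- (v[pos[best]] + v[pos[best] + 1L]) / 2
  left <- v <= cut
  rbind(id3_recurse(v[left], labs[left], min_leaf),
        data.frame(cut = cut, gain = gains[best], n_node = n),
        id3_recurse(v[!left], labs[!left], min_leaf))
}

# Candidate split positions: cut after sorted position p (between distinct
# values) is a boundary point unless the two adjacent value-groups are both
# pure with the same class; both sides must keep >= min_leaf samples.
id3_cut_candidates <- function(v, labs, min_leaf) {
  n <- length(v)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  nruns <- length(ends)
  if (nruns < 2L) return(integer())
  starts <- c(1L, ends[-nruns] + 1L)
  runlab <- vapply(seq_len(nruns), function(j) {
    u <- unique(labs[starts[j]:ends[j]])
    if (length(u) == 1L) u else NA_character_
  }, character(1L))
  j <- seq_len(nruns - 1L)
  boundary <- is.na(runlab[j]) | is.na(runlab[j + 1L]) |
    runlab[j] != runlab[j + 1L]
  pos <- ends[j]
  pos[boundary & pos >= min_leaf & (n - pos) >= min_leaf]
}

# Information gain (bits) of splitting sorted labels after each position.
id3_gains <- function(v, labs, pos) {
  f <- factor(labs)
  n <- length(labs)
  cum <- vapply(levels(f), function(l) cumsum(f == l), numeric(n))
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)
  total <- cum[n, ]
  h <- function(cnt) {
    s <- sum(cnt)
    p <- cnt[cnt > 0] / s
    -sum(p * log2(p))
  }
  hp <- h(total)
  vapply(pos, function(p0) {
    left <- cum[p0, ]
    right <- total - left
    hp - (p0 / n) * h(left) - ((n - p0) / n) * h(right)
  }, numeric(1L))
}

#' Equal-width interval binning (EWIB) cut points for one gene
#'
#' `n_bins - 1` equally spaced cuts between the minimum and maximum of the
#' observed values; a constant gene yields zero cuts.
#'
#' @param values Numeric vector of expression values.
#' @param n_bins Number of bins, `>= 1` (default 5, suited to the small
#'   cohort sizes typical of expression studies).
#' @return Sorted numeric vector of cut points.
#' @export
discretize_gene_ewib <- function(values, n_bins = 5L) {
  check_gene_vector(values)
  if (!is.numeric(n_bins) || n_bins < 1L) ic_validation("'n_bins' must be >= 1")
  rng <- range(values)
  if (rng[1L] == rng[2L] || n_bins == 1L) return(numeric())
  seq(rng[1L], rng[2L], length.out = n_bins + 1L)[-c(1L, n_bins + 1L)]
}

#' Ternary up/normal/down cut points for one gene
#'
#' The coarse baseline discretization: two cuts at `mean - z*sd` and
#' `mean + z*sd` of the gene's values, yielding down/normal/up intervals.
#' The population standard deviation (denominator `n`) is used. A
#' zero-spread gene yields zero cuts.
#'
#' @param values Numeric vector of expression values (length >= 2).
#' @param z Width of the "normal" zone in standard deviations (default 1).
#' @return Numeric vector of 0 or 2 cut points.
#' @export
discretize_gene_ternary <- function(values, z = 1) {
  check_gene_vector(values)
  if (length(values) < 2L) ic_validation("ternary discretization needs >= 2 values")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (s == 0) return(numeric())
  c(m - z * s, m + z * s)
}

#' Pass-through ("NONE") cut points for one gene
#'
#' One degenerate bin per distinct observed value: cuts at midpoints between
#' consecutive distinct values, so each training value keeps its own
#' interval. Intended for data that is already discrete; on continuous data
#' every bin holds a single sample.
#'
#' @param values Numeric vector of expression values.
#' @return Sorted numeric vector of cut points.
#' @export
discretize_gene_none <- function(values) {
  check_gene_vector(values)
  dv <- sort(unique(values))
  if (length(dv) < 2L) return(numeric())
  (dv[-1L] + dv[-length(dv)]) / 2
}

check_gene_vector <- function(values) {
  if (!is.numeric(values) || length(values) < 1L)
    ic_validation("expression vector must be numeric and non-empty")
  if (any(!is.finite(values)))
    ic_validation("expression vector contains non-finite values")
}

#' Build a per-gene interval scheme for a whole matrix
#'
#' Wraps the per-gene cut points of the chosen discretizer into a left-open
#' partition of the real line per gene: with cuts `c1 < ... < ck` the
#' intervals are `(-inf, c1], (c1, c2], ..., (ck, +inf]`, so every real
#' value (including unseen test values outside the training range) maps to
#' exactly one interval.
#'
#' @param x An [expression_matrix()]; class labels are used only by `"id3"`.
#' @param method One of `"id3"`, `"ewib"`, `"none"`, `"ternary"`.
#' @param min_leaf,n_bins,z Parameters forwarded to the per-gene
#'   discretizers.
#' @return An object of class `interval_scheme`: `method`, `params`, `cuts`
#'   (named list of cut vectors) and `range` (named list of observed
#'   training ranges, used by the width-based interval filter).
#' @export
build_scheme <- function(x, method = c("id3", "ewib", "none", "ternary"),
                         min_leaf = 2L, n_bins = 5L, z = 1) {
  method <- match.arg(method)
  genes <- rownames(x$values)
  cuts <- lapply(genes, function(g) {
    v <- x$values[g, ]
    switch(method,
           id3 = discretize_gene_id3(v, x$labels, min_leaf),
           ewib = discretize_gene_ewib(v, n_bins),
           none = discretize_gene_none(v),
           ternary = if (length(v) >= 2L) discretize_gene_ternary(v, z) else numeric())
  })
  names(cuts) <- genes
  rng <- lapply(genes, function(g) range(x$values[g, ]))
  names(rng) <- genes
  structure(list(method = method,
                 params = list(min_leaf = as.integer(min_leaf),
                               n_bins = as.integer(n_bins), z = z),
                 cuts = cuts, range = rng),
            class = "interval_scheme")
}

#' @export
print.interval_scheme <- function(x, ...) {
  k <- lengths(x$cuts) + 1L
  cat(sprintf("<interval_scheme> method %s; %d genes; intervals per gene: median %g, max %d\n",
              x$method, length(x$cuts), stats::median(k), max(k)))
  invisible(x)
}

#' Interval bounds of one gene in a scheme
#' @param scheme An `interval_scheme`.
#' @param gene Gene identifier.
#' @return Data frame with columns `lo`, `hi`; row `i` is interval
#'   `(lo_i, hi_i]`.
#' @export
scheme_intervals <- function(scheme, gene) {
  cuts <- scheme$cuts[[gene]]
  if (is.null(cuts)) ic_validation("gene '%s' is not part of the scheme", gene)
  br <- c(-Inf, cuts, Inf)
  data.frame(lo = br[-length(br)], hi = br[-1L])
}

# Map numeric values to 1-based interval indices under left-open cuts:
# index = #{cuts < x} + 1, so x == cut falls in the interval ending at it.
interval_index <- function(values, cuts) {
  if (!length(cuts)) return(rep(1L, length(values)))
  findInterval(values, cuts, left.open = TRUE) + 1L
}

#' Discretize a matrix under a trained interval scheme
#'
#' Replaces every expression value with the index of the unique interval
#' containing it. Genes absent from the scheme are dropped; genes of the
#' scheme missing from the matrix are an error.
#'
#' @param x An [expression_matrix()] (its labels are carried along; they may
#'   describe a single class for prediction inputs).
#' @param scheme An `interval_scheme` from [build_scheme()].
#' @return An object of class `disc_matrix`: `cells` (integer matrix of
#'   interval indices, genes of the scheme by samples), `labels`, `scheme`.
#' @export
apply_scheme <- function(x, scheme) {
  cells <- discretize_values(x$values, scheme)
  structure(list(cells = cells, labels = x$labels, scheme = scheme),
            class = "disc_matrix")
}

discretize_values <- function(values, scheme) {
  genes <- names(scheme$cuts)
  missing <- setdiff(genes, rownames(values))
  if (length(missing))
    ic_validation("gene '%s' required by the model is absent from the input matrix",
                  missing[1L])
  ns <- ncol(values)
  cells <- t(vapply(genes,
                    function(g) interval_index(values[g, ], scheme$cuts[[g]]),
                    integer(ns)))
  if (ns == 1L) cells <- matrix(cells, ncol = 1L)
  dimnames(cells) <- list(genes, colnames(values))
  cells
}
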