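#' Per-class transaction database of (gene, interval) items
#'
#' Each sample of the chosen class becomes one transaction: the set of
#' (gene, interval-index) items describing it. A transaction holds exactly
#' one item per gene; the item universe is the set of items observed in the
#' class. Item keys are `"<gene>#<interval>"`.
#'
#' @param dm A `disc_matrix` from [apply_scheme()].
#' @param class Class label whose samples form the transactions.
#' @return An object of class `transaction_db`: `mat` (logical transactions
#'   x items matrix with item keys as column names), `items` (data frame
#'   `gene`, `interval`, `key`), `class_label`, `n` (transaction count).
#' @export
build_transactions <- function(dm, class) {
  if (!class %in% dm$labels) ic_validation("unknown class label '%s'", class)
  cells <- dm$cells[, dm$labels == class, drop = FALSE]
  genes <- rownames(cells)
  ng <- nrow(cells); ns <- ncol(cells)
  gene_of <- rep(genes, ns)
  iv <- as.integer(cells)
  keys <- paste0(gene_of, "#", iv)
  univ <- !duplicated(keys)
  items <- data.frame(gene = gene_of[univ], interval = iv[univ],
                      key = keys[univ], stringsAsFactors = FALSE)
  o <- order(items$gene, items$interval)
  items <- items[o, , drop = FALSE]
  rownames(items) <- NULL
  mat <- matrix(FALSE, ns, nrow(items),
                dimnames = list(colnames(cells), items$key))
  mat[cbind(rep(seq_len(ns), each = ng), match(keys, items$key))] <- TRUE
  structure(list(mat = mat, items = items, class_label = class, n = ns),
            class = "transaction_db")
}

#' Support of an itemset in a transaction database
#'
#' Fraction of transactions that are supersets of the itemset. The empty
#' itemset has support 1; items outside the universe have support 0.
#'
#' @param itemset Character vector of item keys (`"<gene>#<interval>"`).
#' @param db A `transaction_db`.
#' @return Fraction in `[0, 1]`.
#' @export
support <- function(itemset, db) {
  if (length(itemset) == 0L) return(1)
  if (db$n == 0L) return(0)
  if (!all(itemset %in% colnames(db$mat))) return(0)
  mean(rowSums(db$mat[, itemset, drop = FALSE]) == length(itemset))
}

#' Drop low-coverage (or narrow) interval items before mining
#'
#' Removes from the transactions every item whose interval is "too small".
#' In the default `"coverage"` mode an item is small when it covers fewer
#' than `min_interval_size` of the class's samples (a scale-free reading of
#' the minimal-interval-size threshold). In `"width"` mode an item is small
#' when its finite interval width is below `min_interval_size` of the
#' gene's observed training range (infinite extreme intervals are always
#' kept).
#'
#' @param db A `transaction_db`.
#' @param min_interval_size Threshold in `[0, 1]` (default 0.05).
#' @param mode `"coverage"` or `"width"`.
#' @param scheme The training `interval_scheme`; required for `"width"`.
#' @return The filtered `transaction_db`.
#' @export
filter_small_intervals <- function(db, min_interval_size = 0.05,
                                   mode = c("coverage", "width"),
                                   scheme = NULL) {
  mode <- match.arg(mode)
  if (min_interval_size < 0 || min_interval_size > 1)
    ic_validation("'min_interval_size' must lie in [0, 1]")
  if (min_interval_size == 0 || db$n == 0L || ncol(db$mat) == 0L) return(db)
  if (mode == "coverage") {
    keep <- colMeans(db$mat) >= min_interval_size
  } else {
    if (is.null(scheme))
      ic_validation("width-based interval filtering needs the interval scheme")
    keep <- vapply(seq_len(nrow(db$items)), function(i) {
      g <- db$items$gene[i]
      iv <- scheme_intervals(scheme, g)[db$items$interval[i], ]
      if (is.infinite(iv$lo) || is.infinite(iv$hi)) return(TRUE)
      rng <- diff(scheme$range[[g]])
      if (rng == 0) return(TRUE)
      (iv$hi - iv$lo) / rng >= min_interval_size
    }, logical(1L))
  }
  db$mat <- db$mat[, keep, drop = FALSE]
  db$items <- db$items[keep, , drop = FALSE]
  rownames(db$items) <- NULL
  db
}

#' Mine the maximal frequent itemsets of a transaction database
#'
#' Depth-first search over the itemset lattice with a bitmap transaction
#' representation, superset pruning against the growing maximal collection
#' and head-union-tail subtree pruning (MAFIA-style). Returns exactly the
#' itemsets that are frequent (support `>= min_support`) and have no
#' frequent proper superset, canonically ordered by size descending then
#' lexicographically, so the output is deterministic.
#'
#' @param db A `transaction_db`.
#' @param min_support Minimum support fraction in `(0, 1]` (default 0.4).
#' @param max_itemsets Guard against pathological inputs: error out if more
#'   maximal itemsets than this are found (default `1e6`).
#' @return An object of class `mfi_set`: `itemsets` (list of character
#'   vectors of item keys, each sorted), `min_support`, `supports` (numeric
#'   vector of the itemsets' supports).
#' @export
mine_mfi <- function(db, min_support = 0.4, max_itemsets = 1e6) {
  if (min_support <= 0 || min_support > 1)
    ic_validation("'min_support' must lie in (0, 1]")
  empty <- structure(list(itemsets = list(), min_support = min_support,
                          supports = numeric()), class = "mfi_set")
  if (db$n == 0L || ncol(db$mat) == 0L) return(empty)
  min_count <- max(1L, as.integer(ceiling(min_support * db$n - 1e-9)))
  raw <- .mine_mfi_cpp(db$mat, min_count, max_itemsets)
  if (!length(raw)) return(empty)
  keys <- colnames(db$mat)
  sets <- lapply(raw, function(ix) sort(keys[ix]))
  sig <- vapply(sets, paste, character(1L), collapse = "\r")
  o <- order(-lengths(sets), sig, method = "radix")
  sets <- sets[o]
  supports <- vapply(raw[o], function(ix) {
    mean(rowSums(db$mat[, ix, drop = FALSE]) == length(ix))
  }, numeric(1L))
  structure(list(itemsets = sets, min_support = min_support,
                 supports = supports), class = "mfi_set")
}

#' @export
print.mfi_set <- function(x, ...) {
  cat(sprintf("<mfi_set> %d maximal frequent itemsets at min support %g\n",
              length(x$itemsets), x$min_support))
  invisible(x)
}

# Split an item key back into its gene and interval index.
split_items <- function(keys) {
  pos <- regexpr("#(?=[0-9]+$)", keys, perl = TRUE)
  list(gene = substr(keys, 1L, pos - 1L),
       interval = as.integer(substr(keys, pos + 1L, nchar(keys))))
}
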