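# Independent oracles used to freeze expected values. These deliberately
# avoid the package's code paths: brute-force enumeration, textbook
# formulas, and stats::t.test.

# Welch p-value via R's reference implementation (independent of the
# package's vectorized formula path).
oracle_welch_p <- function(x, y) {
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

# Brute-force maximal frequent itemsets: test all 2^p - 1 itemsets for
# frequency, then keep the maximal ones. Transactions and itemsets are
# bitmasks over <= 30 items.
oracle_mfi <- function(tmat, min_support) {
  n <- nrow(tmat); p <- ncol(tmat)
  stopifnot(p <= 20L)
  tbits <- apply(tmat, 1L, function(row) sum(2L^(which(row) - 1L)))
  minc <- max(1L, ceiling(min_support * n - 1e-9))
  masks <- seq_len(2L^p - 1L)
  freq <- vapply(masks, function(m) {
    sum(bitwAnd(tbits, m) == m) >= minc
  }, logical(1L))
  fm <- masks[freq]
  maximal <- vapply(fm, function(m) {
    !any(fm != m & bitwAnd(fm, m) == m)
  }, logical(1L))
  lapply(fm[maximal], function(m) which(bitwAnd(2L^(seq_len(p) - 1L), m) > 0L))
}

oracle_frequent <- function(tmat, min_support) {
  n <- nrow(tmat); p <- ncol(tmat)
  tbits <- apply(tmat, 1L, function(row) sum(2L^(which(row) - 1L)))
  minc <- max(1L, ceiling(min_support * n - 1e-9))
  masks <- seq_len(2L^p - 1L)
  fm <- masks[vapply(masks, function(m) sum(bitwAnd(tbits, m) == m) >= minc,
                     logical(1L))]
  lapply(fm, function(m) which(bitwAnd(2L^(seq_len(p) - 1L), m) > 0L))
}

# Brute-force recursive ID3: naive entropy computation, candidates are
# boundary midpoints with >= min_leaf samples per side, identical stopping
# rule and smallest-cut tie-break.
oracle_id3 <- function(values, labels, min_leaf = 2L) {
  ent <- function(l) {
    p <- table(l) / length(l)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  rec <- function(v, l) {
    n <- length(v)
    if (n < 2L * min_leaf || length(unique(l)) < 2L) return(numeric())
    o <- order(v); v <- v[o]; l <- l[o]
    dv <- unique(v)
    cand <- c(); gains <- c()
    for (i in seq_len(length(dv) - 1L)) {
      g1 <- l[v == dv[i]]; g2 <- l[v == dv[i + 1L]]
      pure_same <- length(unique(c(g1, g2))) == 1L
      cut <- (dv[i] + dv[i + 1L]) / 2
      nl <- sum(v <= cut)
      if (pure_same || nl < min_leaf || (n - nl) < min_leaf) next
      gain <- ent(l) - (nl / n) * ent(l[v <= cut]) -
        ((n - nl) / n) * ent(l[v > cut])
      cand <- c(cand, cut); gains <- c(gains, gain)
    }
    if (!length(cand) || max(gains) <= 1e-12) return(numeric())
    best <- cand[which.max(gains)]   # ties: first (smallest cut)
    c(rec(v[v <= best], l[v <= best]), best, rec(v[v > best], l[v > best]))
  }
  sort(rec(values, as.character(labels)))
}

# Random transaction database as a logical matrix.
random_db_matrix <- function(n_trans, n_items, density = 0.5) {
  matrix(stats::runif(n_trans * n_items) < density, n_trans, n_items,
         dimnames = list(NULL, sprintf("g%02d#%d", seq_len(n_items), 1L)))
}

# Wrap a logical matrix as the package's transaction_db structure.
as_transaction_db <- function(mat, class_label = "c") {
  keys <- if (is.null(colnames(mat))) character() else colnames(mat)
  sp <- strsplit(keys, "#", fixed = TRUE)
  items <- data.frame(gene = vapply(sp, `[[`, character(1L), 1L),
                      interval = as.integer(vapply(sp, `[[`, character(1L), 2L)),
                      key = keys, stringsAsFactors = FALSE)
  structure(list(mat = mat, items = items, class_label = class_label,
                 n = nrow(mat)),
            class = "transaction_db")
}

# Small deterministic expression matrix fixture.
toy_matrix <- function(values = NULL, labels = c(s1 = "A", s2 = "A",
                                                 s3 = "B", s4 = "B")) {
  if (is.null(values))
    values <- matrix(c(1, 2, 9, 10,
                       5, 6, 5.5, 6.5,
                       0, 0.1, 3, 3.1), 3, 4, byrow = TRUE,
                     dimnames = list(c("gA", "gB", "gC"), names(labels)))
  expression_matrix(values, labels)
}

# Write raw matrix/label text fixtures (cells given as character so tests
# can plant malformed values); returns the two paths.
write_matrix_fixture <- function(cells, labels, dir = tempfile("fix")) {
  dir.create(dir, showWarnings = FALSE)
  mp <- file.path(dir, "matrix.tsv")
  lp <- file.path(dir, "labels.tsv")
  lines <- c(paste(c("gene", colnames(cells)), collapse = "\t"),
             vapply(seq_len(nrow(cells)), function(i) {
               paste(c(rownames(cells)[i], cells[i, ]), collapse = "\t")
             }, character(1L)))
  writeLines(lines, mp)
  writeLines(paste(names(labels), labels, sep = "\t"), lp)
  list(matrix = mp, labels = lp)
}
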