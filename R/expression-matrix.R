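#' Construct an expression matrix with per-sample class labels
#'
#' The core container of the package: a genes-by-samples real matrix plus a
#' mapping from sample identifier to phenotype class label.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique row names (gene identifiers) and column names (sample
#'   identifiers). All entries must be finite.
#' @param labels Named character vector mapping every sample identifier to a
#'   class label. Names must coincide with `colnames(values)`.
#' @param require_two_classes Require at least two distinct class labels
#'   (the training invariant). Set to `FALSE` only for intermediate objects.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `labels` (reordered to column order).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' x <- expression_matrix(m, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
#' dim(x$values)
#' @export
expression_matrix <- function(values, labels, require_two_classes = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    ic_validation("'values' must be a numeric matrix")
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    ic_validation("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(gid))
    ic_validation("duplicate gene identifier: '%s'", gid[duplicated(gid)][1L])
  if (anyDuplicated(sid))
    ic_validation("duplicate sample identifier: '%s'", sid[duplicated(sid)][1L])
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    ic_validation("non-finite expression value at gene '%s', sample '%s'",
                  gid[bad[1L]], sid[bad[2L]])
  }
  if (is.null(names(labels)))
    ic_validation("'labels' must be a named vector (names are sample ids)")
  labels <- vapply(labels, as.character, character(1L))
  missing <- setdiff(sid, names(labels))
  if (length(missing))
    ic_validation("sample '%s' present in the matrix but has no class label",
                  missing[1L])
  extra <- setdiff(names(labels), sid)
  if (length(extra))
    ic_validation("label file sample '%s' is absent from the matrix", extra[1L])
  labels <- labels[sid]
  if (require_two_classes && length(unique(labels)) < 2L)
    ic_validation("training data must contain at least 2 distinct classes (got %d)",
                  length(unique(labels)))
  structure(list(values = values, labels = labels), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples; classes: %s\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s (%d)", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Number of samples / genes of an expression matrix
#' @param x An `expr_matrix`.
#' @return Integer count.
#' @keywords internal
n_samples <- function(x) ncol(x$values)

class_labels <- function(x) sort(unique(x$labels))

# Subset an expr_matrix by gene ids and/or sample ids (order-preserving).
subset_matrix <- function(x, genes = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  structure(list(values = v, labels = x$labels[colnames(v)]),
            class = "expr_matrix")
}

#' Read an expression matrix and its sample labels from tab-delimited text
#'
#' The matrix file holds sample identifiers in the first row, gene
#' identifiers in the first column, and real-valued cells elsewhere. Lines
#' starting with `#` (GCT-like preamble) are skipped. The labels file has two
#' tab-delimited columns: sample identifier and class label.
#'
#' @param matrix_path Path to the tab-delimited matrix file.
#' @param labels_path Path to the two-column labels file.
#' @param transpose If `TRUE` the matrix file stores samples in rows and is
#'   transposed after parsing (genes-in-rows is the native orientation).
#' @return An [expression_matrix()] object.
#' @export
read_expression_matrix <- function(matrix_path, labels_path, transpose = FALSE) {
  num <- read_matrix_values(matrix_path, transpose)
  labels <- read_labels(labels_path)
  expression_matrix(num, labels)
}

# Label-free matrix parser shared by read_expression_matrix and the
# prediction CLI (prediction inputs carry no class labels).
read_matrix_values <- function(matrix_path, transpose = FALSE) {
  lines <- readLines(matrix_path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) ic_parse("matrix file '%s' has no data rows", matrix_path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1L]]
  body <- parts[-1L]
  width <- lengths(body)
  if (length(unique(width)) != 1L)
    ic_parse("matrix file '%s': ragged rows (line %d has %d fields, line 2 has %d)",
             matrix_path, which(width != width[1L])[1L] + 1L,
             width[width != width[1L]][1L], width[1L])
  ncell <- width[1L] - 1L
  # header may or may not carry a corner label over the gene-id column
  sample_ids <- if (length(header) == ncell + 1L) header[-1L] else header
  if (length(sample_ids) != ncell)
    ic_parse("matrix file '%s': header has %d sample ids but rows have %d value columns",
             matrix_path, length(sample_ids), ncell)
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  cells <- t(vapply(body, function(p) p[-1L], character(ncell)))
  if (ncell == 1L) cells <- matrix(cells, ncol = 1L)
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    ic_parse("matrix file '%s': cannot parse value '%s' at gene '%s', sample '%s'",
             matrix_path, cells[bad[1L], bad[2L]], gene_ids[bad[1L]],
             sample_ids[bad[2L]])
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  if (transpose) num <- t(num)
  num
}

#' Read a two-column sample/class label file
#' @param labels_path Path to a tab-delimited file: sample id, class label.
#' @return Named character vector of class labels.
#' @export
read_labels <- function(labels_path) {
  lines <- readLines(labels_path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    ic_parse("labels file '%s': line %d does not have exactly 2 tab-separated fields",
             labels_path, which(lengths(parts) != 2L)[1L])
  ids <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(ids))
    ic_validation("labels file '%s': duplicate sample id '%s'",
                  labels_path, ids[duplicated(ids)][1L])
  stats::setNames(vapply(parts, `[[`, character(1L), 2L), ids)
}

#' Write an expression matrix (and optionally its labels) to disk
#'
#' @param x An `expr_matrix`.
#' @param matrix_path Output path for the tab-delimited matrix.
#' @param labels_path Optional output path for the two-column label file.
#' @return Invisibly, `x`.
#' @export
write_expression_matrix <- function(x, matrix_path, labels_path = NULL) {
  con <- file(matrix_path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(x$values)), collapse = "\t"), con)
  rows <- vapply(seq_len(nrow(x$values)), function(i) {
    paste(c(rownames(x$values)[i], fmt_num(x$values[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(rows, con)
  if (!is.null(labels_path))
    writeLines(paste(names(x$labels), x$labels, sep = "\t"), labels_path)
  invisible(x)
}

# Shortest decimal representation that round-trips the IEEE double exactly
# (15 significant digits almost always suffice; fall back to 16/17);
# infinities use the explicit -inf/+inf tokens.
fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  for (d in c("%.16g", "%.17g")) {
    bad <- is.finite(x) & suppressWarnings(as.numeric(out)) != x
    if (!any(bad)) break
    out[bad] <- sprintf(d, x[bad])
  }
  out[is.infinite(x) & x < 0] <- "-inf"
  out[is.infinite(x) & x > 0] <- "+inf"
  out[is.na(x)] <- "NA"
  out
}

parse_num <- function(s) {
  out <- suppressWarnings(as.numeric(s))
  out[s %in% c("-inf", "-Inf")] <- -Inf
  out[s %in% c("+inf", "inf", "Inf", "+Inf")] <- Inf
  out
}
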