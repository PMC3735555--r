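#' Construct a single association rule
#'
#' A rule is an implication from a conjunction of (gene, expression interval)
#' items to a class label. Intervals are left-open/right-closed `(lo, hi]`;
#' open-ended bounds are explicit infinities (rendered `-inf` / `+inf` on
#' disk rather than a sentinel magic number).
#'
#' @param genes Character vector of gene identifiers (one item per gene).
#' @param lo,hi Numeric vectors of interval bounds, `lo <= hi`, may be
#'   `-Inf` / `Inf`.
#' @param class Consequent class label.
#' @param support Class-local support of the antecedent in `[0, 1]` (or `NA`).
#' @param confidence Confidence in `[0, 1]` (or `NA`).
#' @return A list of class `ic_rule`.
#' @export
rule <- function(genes, lo, hi, class, support = NA_real_,
                 confidence = NA_real_) {
  if (length(genes) == 0L) ic_validation("rule antecedent must be non-empty")
  if (anyDuplicated(genes))
    ic_validation("rule has more than one item for gene '%s'",
                  genes[duplicated(genes)][1L])
  if (length(lo) != length(genes) || length(hi) != length(genes))
    ic_validation("'lo'/'hi' must match the number of genes")
  if (any(lo > hi)) ic_validation("rule interval with lo > hi")
  for (v in c(support, confidence))
    if (!is.na(v) && (v < 0 || v > 1))
      ic_validation("support/confidence must lie in [0, 1]")
  structure(list(genes = as.character(genes), lo = as.numeric(lo),
                 hi = as.numeric(hi), class = as.character(class),
                 support = as.numeric(support),
                 confidence = as.numeric(confidence)),
            class = "ic_rule")
}

#' @export
format.ic_rule <- function(x, ...) {
  items <- sprintf("%s[%s,%s]", x$genes, fmt_num(x$lo), fmt_num(x$hi))
  paste0(paste(items, collapse = ","), "\t", x$class)
}

#' @export
print.ic_rule <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Write / read association rules as human-auditable text
#'
#' One rule per line: comma-separated `GENE[lo,hi]` items, a tab, the class
#' label, and (in the default `"kv"` format) trailing tab-separated
#' `support=` / `confidence=` key-value fields. The `"plain"` format drops
#' the metadata fields. Bounds are printed at 17 significant digits so a
#' write/read round trip reproduces the rules exactly.
#'
#' @param rules A list of [rule()] objects.
#' @param path Output file path.
#' @param format `"kv"` (with support/confidence) or `"plain"`.
#' @return `write_rules` invisibly returns `rules`; `read_rules` returns a
#'   list of [rule()] objects.
#' @export
write_rules <- function(rules, path, format = c("kv", "plain")) {
  format <- match.arg(format)
  lines <- vapply(rules, function(r) {
    base <- format(r)
    if (format == "kv")
      base <- paste0(base, "\tsupport=", fmt_num(r$support),
                     "\tconfidence=", fmt_num(r$confidence))
    base
  }, character(1L))
  writeLines(lines, path)
  invisible(rules)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  item_re <- "^(.*)\\[([^],]+),([^],]+)\\]$"
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L)
      ic_parse("rules file '%s', line %d: expected items<TAB>class", path, i)
    items <- strsplit(fields[[1L]], ",(?![^\\[]*\\])", perl = TRUE)[[1L]]
    items <- trimws(items)
    m <- regmatches(items, regexec(item_re, items))
    if (any(lengths(m) != 4L))
      ic_parse("rules file '%s', line %d: cannot parse item '%s'",
               path, i, items[lengths(m) != 4L][1L])
    genes <- trimws(vapply(m, `[[`, character(1L), 2L))
    lo <- parse_num(vapply(m, `[[`, character(1L), 3L))
    hi <- parse_num(vapply(m, `[[`, character(1L), 4L))
    if (anyNA(lo) || anyNA(hi))
      ic_parse("rules file '%s', line %d: non-numeric interval bound", path, i)
    support <- confidence <- NA_real_
    for (f in fields[-(1:2)]) {
      kv <- strsplit(f, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L)
        ic_parse("rules file '%s', line %d: bad key-value field '%s'", path, i, f)
      if (kv[[1L]] == "support") support <- parse_num(kv[[2L]])
      else if (kv[[1L]] == "confidence") confidence <- parse_num(kv[[2L]])
      else ic_parse("rules file '%s', line %d: unknown field '%s'", path, i, kv[[1L]])
    }
    out[[i]] <- rule(genes, lo, hi, fields[[2L]], support, confidence)
  }
  out
}
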