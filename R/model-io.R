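#' Persist / restore a trained model as structured text
#'
#' The model file is versioned JSON carrying the config snapshot, class
#' metadata, the per-gene interval scheme and the rules (with their interval
#' bounds, support and confidence), so trained rules stay human-auditable.
#' Writing is deterministic: identical models produce byte-identical files.
#'
#' @param model An `interval_classifier`.
#' @param path Output path.
#' @return `write_model` invisibly returns `path`; `read_model` returns the
#'   restored `interval_classifier`.
#' @export
write_model <- function(model, path) {
  if (!inherits(model, "interval_classifier"))
    ic_validation("'model' must be an interval_classifier")
  sch <- model$scheme
  genes <- names(sch$cuts)
  obj <- list(
    format = "intclass-model",
    format_version = 1L,
    package_version = as.character(packageVersion("intclass")),
    config = unclass(model$config),
    classes = model$classes,
    class_n = as.integer(model$class_n),
    scheme = list(method = sch$method, params = sch$params,
                  genes = genes,
                  cuts = unname(sch$cuts),
                  range = unname(sch$range)),
    rules = lapply(model$rules$rules, function(r) {
      iv <- do.call(rbind, lapply(seq_along(r$genes), function(i) {
        scheme_intervals(sch, r$genes[i])[r$intervals[i], ]
      }))
      list(genes = r$genes, intervals = as.integer(r$intervals),
           lo = fmt_num(iv$lo), hi = fmt_num(iv$hi),
           class = r$class, support = r$support, confidence = r$confidence)
    }),
    min_confidence = model$rules$min_confidence
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) ic_parse("cannot parse model file '%s': %s",
                                               path, conditionMessage(e)))
  if (!identical(obj$format, "intclass-model"))
    ic_parse("'%s' is not an intclass model file", path)
  cfg <- validate_config(obj$config)
  genes <- as.character(unlist(obj$scheme$genes))
  cuts <- lapply(obj$scheme$cuts, function(v) as.numeric(unlist(v)))
  cuts <- lapply(cuts, function(v) if (length(v)) v else numeric())
  if (length(cuts) != length(genes))
    ic_parse("model file '%s': scheme cuts/genes mismatch", path)
  names(cuts) <- genes
  rng <- lapply(obj$scheme$range, function(v) as.numeric(unlist(v)))
  names(rng) <- genes
  scheme <- structure(list(method = obj$scheme$method,
                           params = list(
                             min_leaf = as.integer(obj$scheme$params$min_leaf),
                             n_bins = as.integer(obj$scheme$params$n_bins),
                             z = as.numeric(obj$scheme$params$z)),
                           cuts = cuts, range = rng),
                      class = "interval_scheme")
  classes <- as.character(unlist(obj$classes))
  class_n <- stats::setNames(as.integer(unlist(obj$class_n)), classes)
  rules <- lapply(obj$rules, function(r) {
    list(genes = as.character(unlist(r$genes)),
         intervals = as.integer(unlist(r$intervals)),
         class = r$class, support = as.numeric(r$support),
         confidence = as.numeric(r$confidence))
  })
  structure(list(config = cfg, classes = classes, class_n = class_n,
                 filter = NULL, scheme = scheme,
                 rules = new_rule_set(rules, classes, class_n,
                                      as.numeric(obj$min_confidence))),
            class = "interval_classifier")
}

#' Export a model's rules in the line-oriented rule format
#'
#' Convenience wrapper mapping the model's interval indices to bounds and
#' delegating to [write_rules()].
#'
#' @param model An `interval_classifier`.
#' @param path Output path.
#' @param format Passed to [write_rules()].
#' @return Invisibly, the list of [rule()] objects written.
#' @export
export_model_rules <- function(model, path, format = c("kv", "plain")) {
  rl <- lapply(model$rules$rules, function(r) {
    iv <- do.call(rbind, lapply(seq_along(r$genes), function(i) {
      scheme_intervals(model$scheme, r$genes[i])[r$intervals[i], ]
    }))
    rule(r$genes, iv$lo, iv$hi, r$class, r$support, r$confidence)
  })
  write_rules(rl, path, format)
}
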