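# Strict entity-level evaluation (exact span + exact category, one-to-one
# matching, micro-averaged totals) and a document-level tag consistency
# rate quantifying the repeated-mention inconsistency phenomenon.

entities_of <- function(x) {
  if (inherits(x, "ner_document")) return(stats::setNames(list(x$entities), x$doc_id))
  if (is.data.frame(x)) return(list(doc = x))
  if (is.list(x) && length(x) && inherits(x[[1]], "ner_document")) {
    return(stats::setNames(lapply(x, function(d) d$entities), corpus_ids(x)))
  }
  x
}

prf <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Strict entity-level precision / recall / F1
#'
#' A prediction counts as a true positive iff a gold entity with the
#' identical `(start, end, category)` triple exists in the same document;
#' matching is one-to-one and duplicates are collapsed first. Per-category
#' counts are micro-averaged into the total row.
#'
#' @param gold Gold annotations: a list of [ner_document()] objects, or a
#'   named list (by doc id) of entity data frames.
#' @param predicted Predictions: a named list (by doc id) of entity data
#'   frames, e.g. from [predict.medner()]. Every predicted doc id must exist
#'   in `gold`.
#' @return An object of class `strict_score`: a data frame with one row per
#'   category plus a `total` row and columns `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
strict_prf <- function(gold, predicted) {
  gold <- entities_of(gold)
  predicted <- entities_of(predicted)
  unknown <- setdiff(names(predicted), names(gold))
  if (length(unknown)) {
    stop("predictions for unknown document id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cats <- medner_categories()
  tp <- fp <- fn <- stats::setNames(integer(length(cats)), cats)
  for (id in names(gold)) {
    g <- dedupe_entities(gold[[id]])
    p <- dedupe_entities(predicted[[id]] %||% empty_entities())
    gk <- paste(g$start, g$end, g$category)
    pk <- paste(p$start, p$end, p$category)
    hit <- pk %in% gk
    for (ct in cats) {
      tp[ct] <- tp[ct] + sum(hit & p$category == ct)
      fp[ct] <- fp[ct] + sum(!hit & p$category == ct)
      fn[ct] <- fn[ct] + sum(!(gk %in% pk) & g$category == ct)
    }
  }
  rows <- lapply(cats, function(ct) {
    data.frame(category = ct, tp = tp[ct], fp = fp[ct], fn = fn[ct],
               t(prf(tp[ct], fp[ct], fn[ct])), stringsAsFactors = FALSE)
  })
  total <- data.frame(category = "total", tp = sum(tp), fp = sum(fp),
                      fn = sum(fn), t(prf(sum(tp), sum(fp), sum(fn))),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, c(rows, list(total)))
  rownames(out) <- NULL
  structure(out, class = c("strict_score", "data.frame"))
}

#' @export
print.strict_score <- function(x, ...) {
  cat("Strict entity-level scores (%)\n")
  df <- data.frame(Entity = x$category,
                   P = sprintf("%.2f", 100 * x$precision),
                   R = sprintf("%.2f", 100 * x$recall),
                   F1 = sprintf("%.2f", 100 * x$f1),
                   tp = x$tp, fp = x$fp, fn = x$fn)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a score table as TSV
#'
#' @param score A [strict_prf()] result.
#' @param path Output file.
#' @export
write_score_tsv <- function(score, path) {
  df <- as.data.frame(score)
  df$precision <- round(100 * df$precision, 2)
  df$recall <- round(100 * df$recall, 2)
  df$f1 <- round(100 * df$f1, 2)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Document-level tag consistency rate
#'
#' Over all surface strings predicted as an entity at least twice within the
#' same document, the fraction whose occurrences all carry one category.
#' Returns 1 when no string repeats. A document in which the same mention is
#' tagged anatomy once and drug once scores that string as inconsistent.
#'
#' @param predicted Named list (by doc id) of entity data frames, or a list
#'   of documents whose gold entities should be scored.
#' @return A number in `[0, 1]`.
#' @export
consistency_rate <- function(predicted) {
  predicted <- entities_of(predicted)
  consistent <- 0L; total <- 0L
  for (ents in predicted) {
    if (!nrow(ents)) next
    for (nm in unique(ents$name[duplicated(ents$name)])) {
      total <- total + 1L
      cats <- ents$category[ents$name == nm]
      if (length(unique(cats)) == 1L) consistent <- consistent + 1L
    }
  }
  if (total == 0L) return(1)
  consistent / total
}
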