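# Auxiliary correction passes applied after neural tagging: entity boundary
# auto-correction against an entity base, drug-dictionary longest-match
# rectification/extraction, and boundary post-processing rules.

#' Build an entity base from a training corpus
#'
#' The entity base tallies every (surface form, category) gold occurrence in
#' the training data. It drives boundary auto-correction and gazetteer
#' extraction.
#'
#' @param corpus List of [ner_document()] objects with gold entities.
#' @return A data frame of class `entity_base` with columns `name`,
#'   `category`, `occurrence`.
#' @export
build_entity_base <- function(corpus) {
  corpus <- as_corpus(corpus)
  ents <- do.call(rbind, c(list(empty_entities()),
                           lapply(corpus, function(d) d$entities)))
  entity_base(ents$name, ents$category)
}

entity_base <- function(name, category, occurrence = NULL) {
  if (is.null(occurrence)) {
    if (!length(name)) {
      df <- data.frame(name = character(), category = character(),
                       occurrence = integer(), stringsAsFactors = FALSE)
      return(structure(df, class = c("entity_base", "data.frame")))
    }
    tab <- stats::aggregate(list(occurrence = rep(1L, length(name))),
                            by = list(name = name, category = category), FUN = sum)
  } else {
    tab <- data.frame(name = name, category = category,
                      occurrence = as.integer(occurrence), stringsAsFactors = FALSE)
  }
  if (nrow(tab)) {
    tab$category <- normalize_category(tab$category)
    if (any(tab$occurrence < 1L)) stop("occurrence must be >= 1", call. = FALSE)
    if (any(!nzchar(tab$name))) stop("entity base names must be non-empty", call. = FALSE)
    if (anyDuplicated(paste(tab$name, tab$category))) {
      stop("duplicate (name, category) pair in entity base", call. = FALSE)
    }
    tab <- tab[order(tab$name, tab$category), , drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(tab, class = c("entity_base", "data.frame"))
}

#' Read / write an entity base file
#'
#' Plain TSV with columns `name<TAB>category<TAB>occurrence`, UTF-8.
#'
#' @param path File path.
#' @return `read_entity_base()` returns an entity base; `write_entity_base()`
#'   returns `path` invisibly.
#' @export
read_entity_base <- function(path) {
  lines <- read_utf8(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(entity_base(character(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L)) {
    stop("malformed entity base line(s) in ", path, call. = FALSE)
  }
  entity_base(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L),
              as.integer(vapply(parts, `[`, "", 3L)))
}

#' @param base An entity base.
#' @param labels Category label map used when printing.
#' @rdname read_entity_base
#' @export
write_entity_base <- function(base, path, labels = category_labels()) {
  write_utf8(sprintf("%s\t%s\t%d", base$name, labels[base$category],
                     base$occurrence), path)
  invisible(path)
}

base_lookup <- function(base, name, category = NULL, min_occurrence = 1L) {
  hit <- base$name == name & base$occurrence >= min_occurrence
  if (!is.null(category)) hit <- hit & base$category == category
  base[hit, , drop = FALSE]
}

#' Auto-correct one entity's boundary against the entity base
#'
#' If the recognized (surface form, category) already occurs in the base the
#' entity is trusted and returned unchanged. Otherwise every span whose start
#' lies within `window` characters of the recognized start and whose end lies
#' within `window` characters of the recognized end is considered; spans
#' whose surface form occurs in the base are candidates. Candidates of the
#' entity's own category are preferred, then higher base occurrence, then
#' longer spans, then the leftmost. If no candidate exists the entity is
#' returned unchanged.
#'
#' @param entity A one-row entity data frame.
#' @param text The owning document's text.
#' @param base An entity base (see [build_entity_base()]).
#' @param window Maximum boundary shift in characters (default 3;
#'   `window = 0` makes the correction the identity).
#' @param adopt_category If `TRUE`, a candidate found only under another
#'   category is accepted and the entity re-categorized (the base's tags are
#'   assumed authoritative). Default `FALSE`: boundary-only correction.
#' @param min_occurrence Minimum base occurrence for an entry to be trusted.
#' @return A one-row entity data frame (corrected or unchanged).
#' @export
#' @examples
#' base <- build_entity_base(list(ner_document("查见左附件区。",
#'   entity_frame("左附件区", 2, 6, "anatomy"))))
#' doc <- ner_document("查见左附件区。")
#' autocorrect_entity(entity_frame("左附件", 2, 5, "anatomy"), doc$text, base)
autocorrect_entity <- function(entity, text, base, window = 3L,
                               adopt_category = FALSE, min_occurrence = 1L) {
  stopifnot(nrow(entity) == 1L)
  if (window <= 0L || nrow(base) == 0L) return(entity)
  if (nrow(base_lookup(base, entity$name, entity$category, min_occurrence))) {
    return(entity)
  }
  n <- n_chars(text)
  starts <- max(0L, entity$start - window):min(n - 1L, entity$start + window)
  ends <- max(1L, entity$end - window):min(n, entity$end + window)
  cand <- expand.grid(start = starts, end = ends)
  cand <- cand[cand$start < cand$end &
                 !(cand$start == entity$start & cand$end == entity$end), , drop = FALSE]
  if (!nrow(cand)) return(entity)
  cand$name <- slice_text(text, cand$start, cand$end)
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    hits <- base_lookup(base, cand$name[i], entity$category, min_occurrence)
    same_cat <- nrow(hits) > 0L
    if (!same_cat && adopt_category) {
      hits <- base_lookup(base, cand$name[i], NULL, min_occurrence)
    }
    if (!nrow(hits)) next
    hits <- hits[order(-hits$occurrence, hits$category), , drop = FALSE]
    key <- c(as.integer(same_cat), hits$occurrence[1],
             cand$end[i] - cand$start[i], -cand$start[i])
    if (is.null(best) || lex_greater(key, best$key)) {
      best <- list(key = key, start = cand$start[i], end = cand$end[i],
                   name = cand$name[i],
                   category = if (same_cat) entity$category else hits$category[1])
    }
  }
  if (is.null(best)) return(entity)
  entity_frame(best$name, best$start, best$end, best$category)
}

lex_greater <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i]) return(TRUE)
    if (a[i] < b[i]) return(FALSE)
  }
  FALSE
}

#' Read a drug dictionary file
#'
#' One drug name per line, UTF-8; lines starting with `#` are comments.
#'
#' @param path File path.
#' @return A character vector of drug names.
#' @export
read_drug_dictionary <- function(path) {
  lines <- read_utf8(path)
  unique(lines[nzchar(lines) & !startsWith(lines, "#")])
}

is_ascii <- function(x) !grepl("[^\x01-\x7F]", x)

#' Longest-match drug extraction
#'
#' Scans the text left to right; at each position the longest dictionary
#' name matching there is emitted and the scan resumes after it, so shorter
#' names contained in longer ones (e.g. `CPT` inside `CPT-11`) are
#' suppressed. Matching is case-insensitive for pure-ASCII dictionary
#' entries (English abbreviations) and exact otherwise.
#'
#' @param text Document text.
#' @param dict Character vector of drug names.
#' @return An entity data frame with `category = "drug"`.
#' @export
#' @examples
#' match_drugs("给予CPT-11治疗。", c("CPT", "CPT-11"))
match_drugs <- function(text, dict) {
  dict <- dict[nzchar(dict)]
  if (!length(dict)) return(empty_entities())
  chars <- split_chars(text)
  lower <- tolower(chars)
  n <- length(chars)
  dlen <- nchar(dict, type = "chars")
  ord <- order(-dlen)
  dict <- dict[ord]; dlen <- dlen[ord]
  dkey <- ifelse(is_ascii(dict), tolower(dict), dict)
  out_s <- integer(0); out_e <- integer(0)
  pos <- 1L
  while (pos <= n) {
    hit_len <- 0L
    for (i in seq_along(dict)) {
      L <- dlen[i]
      if (pos + L - 1L > n) next
      cand <- paste(chars[pos:(pos + L - 1L)], collapse = "")
      cand_key <- if (is_ascii(dict[i])) paste(lower[pos:(pos + L - 1L)], collapse = "") else cand
      if (cand_key == dkey[i]) { hit_len <- L; break }
    }
    if (hit_len > 0L) {
      out_s <- c(out_s, pos - 1L); out_e <- c(out_e, pos - 1L + hit_len)
      pos <- pos + hit_len
    } else {
      pos <- pos + 1L
    }
  }
  entity_frame(slice_text(text, out_s, out_e), out_s, out_e,
               rep("drug", length(out_s)))
}

spans_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

#' Reconcile predicted drug entities with dictionary matches
#'
#' The dictionary acts as a second authentication factor for drug entities:
#' a predicted drug overlapping a dictionary match is replaced by the match
#' (boundary rectification); matches overlapping no prediction are added
#' (extraction); predicted drugs not contradicted by the dictionary are
#' kept. Non-drug predictions are untouched unless they coincide exactly
#' with a match span, in which case they are re-categorized as drug.
#'
#' @param predicted Entity data frame of model predictions for one document.
#' @param dict_matches Result of [match_drugs()] on the same document.
#' @return The reconciled entity data frame.
#' @export
merge_drug_entities <- function(predicted, dict_matches) {
  if (nrow(dict_matches) == 0L) return(predicted)
  keep <- logical(nrow(predicted))
  cat_out <- predicted$category
  for (i in seq_len(nrow(predicted))) {
    ov <- spans_overlap(predicted$start[i], predicted$end[i],
                        dict_matches$start, dict_matches$end)
    if (predicted$category[i] == "drug") {
      keep[i] <- !any(ov)           # overlapping predictions yield to the match
    } else {
      exact <- dict_matches$start == predicted$start[i] &
        dict_matches$end == predicted$end[i]
      if (any(exact)) cat_out[i] <- "drug"
      keep[i] <- TRUE
    }
  }
  out <- predicted
  out$category <- cat_out
  out <- out[keep, , drop = FALSE]
  out <- rbind(out, dict_matches)
  dedupe_entities(out)
}

dedupe_entities <- function(entities) {
  if (!nrow(entities)) return(entities)
  key <- paste(entities$start, entities$end, entities$category)
  entities <- entities[!duplicated(key), , drop = FALSE]
  entities <- entities[order(entities$start, entities$end, entities$category), , drop = FALSE]
  rownames(entities) <- NULL
  entities
}

#' Default boundary post-processing rules
#'
#' Four rule kinds applied in order: `strip_suffix` removes a trailing token
#' from entities of the scoped category (the "旁" rule); `prefix_merge`
#' absorbs an orientation phrase immediately before an anatomy entity;
#' `suffix_merge` absorbs an orientation phrase after an anatomy entity or a
#' "术"/"手术" phrase after a surgery entity; `gazetteer_extract` scans the
#' text for anatomy and surgery names from the entity base that the model
#' missed. Token lists are open and configurable; the defaults are the
#' standard orientation and surgery phrases.
#'
#' @return A list of rule specifications (`kind`, `category`, `tokens`).
#' @export
default_rules <- function() {
  list(
    list(kind = "strip_suffix", category = "anatomy", tokens = c("旁")),
    list(kind = "prefix_merge", category = "anatomy",
         tokens = c("右上", "左上", "右", "左")),
    list(kind = "suffix_merge", category = "anatomy",
         tokens = c("周", "上", "下", "外")),
    list(kind = "suffix_merge", category = "surgery", tokens = c("手术", "术")),
    list(kind = "gazetteer_extract", category = c("anatomy", "surgery"),
         tokens = character(0))
  )
}

#' Read / write a rules file
#'
#' Rules are stored as YAML: a list of mappings with fields `kind`,
#' `category` and `tokens`.
#'
#' @param path File path.
#' @return `read_rules()` returns a rule list shaped like [default_rules()].
#' @export
read_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(r) {
    kind <- match.arg(r$kind, c("strip_suffix", "prefix_merge", "suffix_merge",
                                "gazetteer_extract"))
    tokens <- as.character(r$tokens %||% character(0))
    if (kind != "gazetteer_extract" && !length(tokens)) {
      stop("rule '", kind, "' requires a non-empty token list", call. = FALSE)
    }
    list(kind = kind, category = normalize_category(as.character(r$category)),
         tokens = tokens)
  })
}

#' @param rules A rule list.
#' @rdname read_rules
#' @export
write_rules <- function(rules, path) {
  yaml::write_yaml(lapply(rules, function(r) {
    list(kind = r$kind, category = as.list(r$category), tokens = as.list(r$tokens))
  }), path)
  invisible(path)
}

#' Apply boundary post-processing rules
#'
#' @param entities Entity data frame of predictions for one document.
#' @param text The document text.
#' @param rules Rule list, see [default_rules()].
#' @param base Entity base used by `gazetteer_extract` rules (may be `NULL`
#'   when no such rule is present).
#' @return The corrected, de-duplicated entity data frame.
#' @export
apply_rules <- function(entities, text, rules = default_rules(), base = NULL) {
  n <- n_chars(text)
  for (rule in rules) {
    if (rule$kind == "gazetteer_extract") {
      entities <- rule_gazetteer_extract(entities, text, rule$category, base)
      next
    }
    toks <- rule$tokens[order(-nchar(rule$tokens, type = "chars"))]
    in_scope <- entities$category %in% rule$category
    for (i in which(in_scope)) {
      # repeat until no token fires, so a single pass reaches the fixed
      # point and the pipeline stays idempotent
      repeat {
        fired <- FALSE
        for (tok in toks) {
          L <- nchar(tok, type = "chars")
          if (rule$kind == "strip_suffix") {
            if (entities$end[i] - entities$start[i] > L &&
                slice_text(text, entities$end[i] - L, entities$end[i]) == tok) {
              entities$end[i] <- entities$end[i] - L
              fired <- TRUE
              break
            }
          } else if (rule$kind == "prefix_merge") {
            s <- entities$start[i] - L
            if (s >= 0L && slice_text(text, s, entities$start[i]) == tok) {
              entities$start[i] <- s
              fired <- TRUE
              break
            }
          } else if (rule$kind == "suffix_merge") {
            e <- entities$end[i] + L
            if (e <= n && slice_text(text, entities$end[i], e) == tok) {
              entities$end[i] <- e
              fired <- TRUE
              break
            }
          }
        }
        if (!fired) break
      }
    }
    entities$name <- slice_text(text, entities$start, entities$end)
  }
  dedupe_entities(entities)
}

# leftmost-longest scan for base names of the scoped categories that do not
# overlap any existing prediction
rule_gazetteer_extract <- function(entities, text, categories, base) {
  if (is.null(base) || !nrow(base)) return(entities)
  sub <- base[base$category %in% categories, , drop = FALSE]
  if (!nrow(sub)) return(entities)
  chars <- split_chars(text)
  n <- length(chars)
  lens <- nchar(sub$name, type = "chars")
  ord <- order(-lens)
  sub <- sub[ord, , drop = FALSE]; lens <- lens[ord]
  add_s <- integer(0); add_e <- integer(0); add_c <- character(0)
  pos <- 1L
  while (pos <= n) {
    hit <- 0L; hit_cat <- NA_character_
    for (i in seq_len(nrow(sub))) {
      L <- lens[i]
      if (pos + L - 1L > n) next
      if (paste(chars[pos:(pos + L - 1L)], collapse = "") == sub$name[i]) {
        hit <- L
        cands <- sub[sub$name == sub$name[i], , drop = FALSE]
        hit_cat <- cands$category[which.max(cands$occurrence)]
        break
      }
    }
    if (hit > 0L) {
      s <- pos - 1L; e <- pos - 1L + hit
      if (!any(spans_overlap(s, e, entities$start, entities$end))) {
        add_s <- c(add_s, s); add_e <- c(add_e, e); add_c <- c(add_c, hit_cat)
      }
      pos <- pos + hit
    } else {
      pos <- pos + 1L
    }
  }
  if (length(add_s)) {
    entities <- rbind(entities,
                      entity_frame(slice_text(text, add_s, add_e), add_s, add_e, add_c))
  }
  dedupe_entities(entities)
}

#' Run the full post-processing pipeline on one document
#'
#' Applies the three auxiliary measures in the configured order (default:
#' auto-correct, then drug-dictionary reconciliation, then boundary rules),
#' de-duplicates, and returns entities sorted by span. Each order is
#' idempotent: applying the pipeline to its own output changes nothing.
#'
#' @param predicted Entity data frame of model predictions for one document.
#' @param text Document text.
#' @param base Entity base ([build_entity_base()] result), or `NULL` to skip
#'   auto-correct and gazetteer extraction.
#' @param dict Drug dictionary (character vector), or `NULL` to skip.
#' @param rules Rule list, or `NULL` to skip the rule pass.
#' @param order Character vector permutation of
#'   `c("autocorrect", "dictionary", "rules")`.
#' @param window,adopt_category,min_occurrence Passed to
#'   [autocorrect_entity()].
#' @return The post-processed entity data frame.
#' @export
postprocess_entities <- function(predicted, text, base = NULL, dict = NULL,
                                 rules = default_rules(),
                                 order = c("autocorrect", "dictionary", "rules"),
                                 window = 3L, adopt_category = FALSE,
                                 min_occurrence = 1L) {
  order <- match.arg(order, c("autocorrect", "dictionary", "rules"),
                     several.ok = TRUE)
  ents <- dedupe_entities(predicted)
  # iterate the configured pass order to a fixed point (one pass of a later
  # measure can expose work for an earlier one), so every order is idempotent
  for (iter in 1:10) {
    prev <- ents
    for (step in order) {
      if (step == "autocorrect" && !is.null(base)) {
        if (nrow(ents)) {
          ents <- do.call(rbind, lapply(seq_len(nrow(ents)), function(i) {
            autocorrect_entity(ents[i, , drop = FALSE], text, base,
                               window = window, adopt_category = adopt_category,
                               min_occurrence = min_occurrence)
          }))
        }
        ents <- dedupe_entities(ents)
      } else if (step == "dictionary" && !is.null(dict)) {
        ents <- merge_drug_entities(ents, match_drugs(text, dict))
      } else if (step == "rules" && !is.null(rules)) {
        ents <- apply_rules(ents, text, rules, base)
      }
    }
    ents <- dedupe_entities(ents)
    if (identical(ents, prev)) break
  }
  ents
}

#' Post-process predictions for a whole corpus
#'
#' @param predictions Named list of entity data frames (as returned by
#'   [predict.medner()]).
#' @param corpus The corresponding list of [ner_document()] objects.
#' @param ... Passed on to [postprocess_entities()].
#' @return A named list of post-processed entity data frames.
#' @export
postprocess_corpus <- function(predictions, corpus, ...) {
  corpus <- as_corpus(corpus)
  ids <- corpus_ids(corpus)
  out <- lapply(seq_along(corpus), function(i) {
    postprocess_entities(predictions[[ids[i]]] %||% empty_entities(),
                         corpus[[i]]$text, ...)
  })
  names(out) <- ids
  out
}
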