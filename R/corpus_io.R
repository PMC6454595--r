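# Reading and writing clinical documents, tagged-item annotations and
# CoNLL-style BIO column files; sentence splitting; BIO encoding/decoding.
#
# All character offsets are 0-based, half-open [start, end), counted in
# Unicode code points. Files are UTF-8.

#' Create an entity table
#'
#' Entities are kept as plain data frames with columns `name`, `start`, `end`
#' and `category`. `start`/`end` are 0-based, half-open code-point offsets
#' into the owning document's text.
#'
#' @param name Character vector of surface forms.
#' @param start,end Integer offsets, `0 <= start < end`.
#' @param category Entity categories; Chinese labels are normalized to the
#'   canonical identifiers of [medner_categories()].
#' @return A data frame with one row per entity.
#' @export
#' @examples
#' entity_frame("胃", 12, 13, "anatomy")
entity_frame <- function(name = character(), start = integer(),
                         end = integer(), category = character()) {
  df <- data.frame(name = as.character(name),
                   start = as.integer(start),
                   end = as.integer(end),
                   category = if (length(category)) normalize_category(as.character(category)) else character(),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

empty_entities <- function() entity_frame()

validate_entities <- function(entities, text, where = "document") {
  if (nrow(entities) == 0) return(invisible(entities))
  n <- n_chars(text)
  bad <- entities$start < 0 | entities$end > n | entities$start >= entities$end
  if (any(bad)) {
    stop("invalid entity span(s) in ", where, ": ",
         paste(sprintf("[%d,%d)", entities$start[bad], entities$end[bad]), collapse = ", "),
         call. = FALSE)
  }
  got <- slice_text(text, entities$start, entities$end)
  mism <- got != entities$name
  if (any(mism)) {
    stop("entity name does not match text slice in ", where, ": ",
         paste(sprintf("'%s' vs text '%s' at [%d,%d)", entities$name[mism],
                       got[mism], entities$start[mism], entities$end[mism]),
               collapse = "; "),
         call. = FALSE)
  }
  key <- paste(entities$start, entities$end, entities$category)
  if (anyDuplicated(key)) {
    stop("duplicate (start, end, category) entity in ", where, call. = FALSE)
  }
  invisible(entities)
}

#' Parse one tagged-item annotation line
#'
#' The annotation format carries one entity per line as
#' `name<TAB>start<TAB>end<TAB>category`. Offsets in the file are interpreted
#' relative to `offset_base` (annotations in the wild are sometimes 1-based)
#' and stored 0-based.
#'
#' @param line A single annotation line.
#' @param offset_base Integer base of the offsets in the file (default 0).
#' @return A one-row entity data frame (see [entity_frame()]).
#' @export
#' @examples
#' parse_tagged_item("胃\t12\t13\t解剖部位")
parse_tagged_item <- function(line, offset_base = 0L) {
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(fields) != 4L) {
    stop("malformed tagged item (expected 4 tab-separated fields, got ",
         length(fields), "): '", line, "'", call. = FALSE)
  }
  start <- suppressWarnings(as.integer(fields[2]))
  end <- suppressWarnings(as.integer(fields[3]))
  if (is.na(start) || is.na(end) ||
      fields[2] != as.character(start) || fields[3] != as.character(end) ||
      start < 0L || end < 0L) {
    stop("malformed tagged item (offsets must be non-negative integers): '",
         line, "'", call. = FALSE)
  }
  entity_frame(fields[1], start - as.integer(offset_base),
               end - as.integer(offset_base), fields[4])
}

#' Parse a tagged-item annotation file
#'
#' @param x A file path or a character vector of annotation lines.
#' @param offset_base Offset base of the file; see [parse_tagged_item()].
#' @return An entity data frame with one row per line.
#' @export
parse_tagged_items <- function(x, offset_base = 0L) {
  lines <- if (length(x) == 1L && file.exists(x)) read_utf8(x) else x
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_entities())
  do.call(rbind, lapply(lines, parse_tagged_item, offset_base = offset_base))
}

#' Write entities in the tagged-item format
#'
#' Inverse of [parse_tagged_items()]: writing the result of a parse
#' reproduces a well-formed input file byte for byte (for files using the
#' same category labels and offset base).
#'
#' @param entities Entity data frame.
#' @param path Optional output file; if `NULL` the lines are returned.
#' @param labels Named map from canonical categories to the labels to print;
#'   defaults to the Chinese task labels.
#' @param offset_base Offset base to print.
#' @return Invisibly (or visibly when `path` is `NULL`) the formatted lines.
#' @export
write_tagged_items <- function(entities, path = NULL, labels = category_labels(),
                               offset_base = 0L) {
  lines <- if (nrow(entities) == 0) character(0) else {
    sprintf("%s\t%d\t%d\t%s", entities$name,
            entities$start + as.integer(offset_base),
            entities$end + as.integer(offset_base),
            labels[entities$category])
  }
  if (is.null(path)) return(lines)
  write_utf8(lines, path)
  invisible(lines)
}

read_utf8 <- function(path) {
  con <- file(path, encoding = "UTF-8")
  on.exit(close(con))
  enc2utf8(readLines(con, warn = FALSE))
}

write_utf8 <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

#' Split text into sentence spans
#'
#' Splits after any of the delimiters `。 ； ！ ？` or newline; the delimiter
#' stays with the preceding span. The returned spans are non-overlapping,
#' ordered, and concatenate back to the full text.
#'
#' @param text A single string.
#' @return An integer matrix with columns `start`, `end` (0-based, half-open).
#' @export
#' @examples
#' split_sentences("腹痛。发热")
split_sentences <- function(text) {
  text <- enc2utf8(text)
  chars <- split_chars(text)
  n <- length(chars)
  if (n == 0L) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  delim <- chars %in% c("。", "；", "！", "？", "\n")
  cuts <- c(0L, which(delim), n)
  cuts <- unique(cuts)
  spans <- cbind(start = cuts[-length(cuts)], end = cuts[-1])
  spans <- spans[spans[, "end"] > spans[, "start"], , drop = FALSE]
  spans
}

# merge sentence spans so that no entity crosses a sentence boundary
merge_spans_for_entities <- function(spans, entities) {
  if (nrow(spans) <= 1L || nrow(entities) == 0L) return(spans)
  repeat {
    crossing <- FALSE
    for (i in seq_len(nrow(entities))) {
      s <- entities$start[i]; e <- entities$end[i]
      first <- which(spans[, "start"] <= s & s < spans[, "end"])
      last <- which(spans[, "start"] < e & e <= spans[, "end"])
      if (length(first) != 1L || length(last) != 1L) next
      if (first != last) {
        spans <- rbind(
          spans[seq_len(first - 1L), , drop = FALSE],
          c(spans[first, "start"], spans[last, "end"]),
          if (last < nrow(spans)) spans[(last + 1L):nrow(spans), , drop = FALSE]
        )
        colnames(spans) <- c("start", "end")
        crossing <- TRUE
        break
      }
    }
    if (!crossing) break
  }
  spans
}

#' Create a clinical document
#'
#' Bundles raw text, sentence spans and (optionally) gold entities. Sentences
#' are produced by [split_sentences()]; a sentence split that would cut
#' through a gold entity is merged so every entity is sentence-internal.
#'
#' @param text Document text (UTF-8).
#' @param entities Optional entity data frame (gold annotations).
#' @param doc_id Document identifier.
#' @return An object of class `ner_document`.
#' @export
ner_document <- function(text, entities = NULL, doc_id = "doc") {
  text <- enc2utf8(text)
  if (is.null(entities)) entities <- empty_entities()
  entities <- entities[order(entities$start, entities$end), , drop = FALSE]
  rownames(entities) <- NULL
  validate_entities(entities, text, where = paste0("document '", doc_id, "'"))
  spans <- merge_spans_for_entities(split_sentences(text), entities)
  structure(list(doc_id = doc_id, text = text,
                 sentence_spans = spans, entities = entities),
            class = "ner_document")
}

#' @export
print.ner_document <- function(x, ...) {
  cat("<ner_document '", x$doc_id, "': ", n_chars(x$text), " chars, ",
      nrow(x$sentence_spans), " sentences, ", nrow(x$entities),
      " gold entities>\n", sep = "")
  invisible(x)
}

as_corpus <- function(x) {
  if (inherits(x, "ner_document")) list(x) else x
}

corpus_ids <- function(corpus) vapply(corpus, function(d) d$doc_id, character(1))

#' Encode a document's gold entities as BIO tag sequences
#'
#' The first character of an entity receives `B-<cat>`, subsequent characters
#' `I-<cat>`, all other characters `O`. Entities must be non-overlapping and
#' sentence-internal.
#'
#' @param document An [ner_document()].
#' @return A list with one character vector of tags per sentence; lengths
#'   match sentence lengths.
#' @export
encode_bio <- function(document) {
  ents <- document$entities
  if (nrow(ents) > 1L) {
    ov <- which(ents$start[-1] < ents$end[-nrow(ents)])
    if (length(ov)) {
      stop("overlapping entities: ",
           paste(sprintf("[%d,%d) '%s' vs [%d,%d) '%s'",
                         ents$start[ov], ents$end[ov], ents$name[ov],
                         ents$start[ov + 1], ents$end[ov + 1], ents$name[ov + 1]),
                 collapse = "; "),
           call. = FALSE)
    }
  }
  spans <- document$sentence_spans
  tags_doc <- rep("O", n_chars(document$text))
  for (i in seq_len(nrow(ents))) {
    s <- ents$start[i]; e <- ents$end[i]
    inside <- which(spans[, "start"] <= s & e <= spans[, "end"])
    if (!length(inside)) {
      stop("entity [", s, ",", e, ") '", ents$name[i],
           "' crosses a sentence boundary", call. = FALSE)
    }
    cat_i <- ents$category[i]
    tags_doc[s + 1L] <- bio_labels(cat_i, "B")
    if (e - s > 1L) tags_doc[(s + 2L):e] <- bio_labels(cat_i, "I")
  }
  lapply(seq_len(nrow(spans)), function(j) {
    tags_doc[(spans[j, "start"] + 1L):spans[j, "end"]]
  })
}

#' Decode BIO tag sequences into entities
#'
#' Maximal `B-X (I-X)*` runs become entities with document-level offsets. An
#' `I-X` that does not continue a same-category run is decoded leniently as
#' opening a new entity, with a warning.
#'
#' @param tags List of per-sentence character tag vectors (as produced by
#'   [encode_bio()] or by the tagger).
#' @param document The owning [ner_document()] (supplies text and offsets).
#' @return An entity data frame.
#' @export
decode_bio <- function(tags, document) {
  ts <- medner_tags()
  spans <- document$sentence_spans
  if (length(tags) != nrow(spans)) {
    stop("tag sequence count (", length(tags), ") does not match sentence count (",
         nrow(spans), ")", call. = FALSE)
  }
  out_start <- integer(0); out_end <- integer(0); out_cat <- character(0)
  lenient <- 0L
  for (j in seq_along(tags)) {
    tg <- tags[[j]]
    if (!all(tg %in% ts$labels)) {
      stop("unknown tag label(s): ",
           paste(unique(tg[!tg %in% ts$labels]), collapse = ", "), call. = FALSE)
    }
    if (length(tg) != spans[j, "end"] - spans[j, "start"]) {
      stop("tag sequence length mismatch in sentence ", j, call. = FALSE)
    }
    off <- spans[j, "start"]
    cur_cat <- NA_character_; cur_start <- NA_integer_
    for (t in seq_along(tg)) {
      lab <- tg[t]
      if (lab == "O") {
        if (!is.na(cur_cat)) {
          out_start <- c(out_start, cur_start); out_end <- c(out_end, off + t - 1L)
          out_cat <- c(out_cat, cur_cat); cur_cat <- NA_character_
        }
      } else {
        kind <- substr(lab, 1, 1)
        cat_t <- tag_category(lab)
        if (kind == "B" || is.na(cur_cat) || cat_t != cur_cat) {
          if (kind == "I") lenient <- lenient + 1L
          if (!is.na(cur_cat)) {
            out_start <- c(out_start, cur_start); out_end <- c(out_end, off + t - 1L)
            out_cat <- c(out_cat, cur_cat)
          }
          cur_cat <- cat_t; cur_start <- off + t - 1L
        }
        # an I- continuing the current category extends the open run
      }
    }
    if (!is.na(cur_cat)) {
      out_start <- c(out_start, cur_start); out_end <- c(out_end, spans[j, "end"])
      out_cat <- c(out_cat, cur_cat)
    }
  }
  if (lenient > 0L) {
    warning(lenient, " I- tag(s) did not continue a same-category run; ",
            "decoded as new entities", call. = FALSE)
  }
  entity_frame(slice_text(document$text, out_start, out_end),
               out_start, out_end, out_cat)
}

# BIO column files: "char<TAB>tag" per token, blank line between sentences,
# an additional blank line between documents. Literal newline / tab tokens
# are escaped as "\n" / "\t".
escape_token <- function(x) {
  x[x == "\n"] <- "\\n"; x[x == "\t"] <- "\\t"; x
}
unescape_token <- function(x) {
  x[x == "\\n"] <- "\n"; x[x == "\\t"] <- "\t"; x
}

#' Write documents as a CoNLL-style BIO column file
#'
#' @param corpus A list of [ner_document()] objects (or a single document).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bio <- function(corpus, path) {
  corpus <- as_corpus(corpus)
  out <- character(0)
  for (d in corpus) {
    tags <- encode_bio(d)
    spans <- d$sentence_spans
    for (j in seq_len(nrow(spans))) {
      chars <- split_chars(slice_text(d$text, spans[j, "start"], spans[j, "end"]))
      out <- c(out, paste0(escape_token(chars), "\t", tags[[j]]), "")
    }
    out <- c(out, "")
  }
  write_utf8(out, path)
}

#' Read a CoNLL-style BIO column file
#'
#' @param path Input file written by [write_bio()].
#' @param doc_ids Optional document identifiers.
#' @return A list of [ner_document()] objects with entities recovered from
#'   the tags.
#' @export
read_bio <- function(path, doc_ids = NULL) {
  lines <- read_utf8(path)
  docs <- list(); cur_sents <- list(); cur_tags <- list()
  tok <- character(0); tg <- character(0)
  blank_run <- 0L
  flush_sentence <- function() {
    if (length(tok)) {
      cur_sents[[length(cur_sents) + 1L]] <<- tok
      cur_tags[[length(cur_tags) + 1L]] <<- tg
      tok <<- character(0); tg <<- character(0)
    }
  }
  flush_document <- function() {
    flush_sentence()
    if (length(cur_sents)) {
      docs[[length(docs) + 1L]] <<- list(sents = cur_sents, tags = cur_tags)
      cur_sents <<- list(); cur_tags <<- list()
    }
  }
  for (ln in lines) {
    if (!nzchar(ln)) {
      blank_run <- blank_run + 1L
      if (blank_run == 1L) flush_sentence() else flush_document()
      next
    }
    blank_run <- 0L
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed BIO line: '", ln, "'", call. = FALSE)
    tok <- c(tok, unescape_token(parts[1])); tg <- c(tg, parts[2])
  }
  flush_document()
  if (is.null(doc_ids)) doc_ids <- sprintf("doc%03d", seq_along(docs))
  out <- vector("list", length(docs))
  for (i in seq_along(docs)) {
    text <- paste(vapply(docs[[i]]$sents, paste, character(1), collapse = ""),
                  collapse = "")
    doc <- ner_document(text, doc_id = doc_ids[i])
    # impose the file's sentence boundaries (they may differ from the splitter's)
    lens <- vapply(docs[[i]]$sents, length, integer(1))
    ends <- cumsum(lens)
    doc$sentence_spans <- cbind(start = c(0L, ends[-length(ends)]), end = ends)
    doc$entities <- decode_bio(docs[[i]]$tags, doc)
    out[[i]] <- doc
  }
  out
}

#' Write a corpus as raw text plus tagged-item files
#'
#' Each document `d` becomes `<doc_id>.txt` (raw UTF-8 text) and
#' `<doc_id>.tsv` (tagged-item annotations).
#'
#' @param corpus List of [ner_document()] objects.
#' @param dir Output directory (created if missing).
#' @param labels,offset_base Passed to [write_tagged_items()].
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir, labels = category_labels(), offset_base = 0L) {
  corpus <- as_corpus(corpus)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (d in corpus) {
    write_utf8(d$text, file.path(dir, paste0(d$doc_id, ".txt")))
    write_tagged_items(d$entities, file.path(dir, paste0(d$doc_id, ".tsv")),
                       labels = labels, offset_base = offset_base)
  }
  invisible(dir)
}

#' Read a corpus written by [write_corpus()]
#'
#' @param dir Directory containing `<doc_id>.txt` (and optionally
#'   `<doc_id>.tsv`) files.
#' @param offset_base Offset base of the annotation files.
#' @return A list of [ner_document()] objects, ordered by file name.
#' @export
read_corpus <- function(dir, offset_base = 0L) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  lapply(txts, function(f) {
    doc_id <- sub("\\.txt$", "", basename(f))
    text <- paste(read_utf8(f), collapse = "\n")
    tsv <- file.path(dir, paste0(doc_id, ".tsv"))
    ents <- if (file.exists(tsv)) parse_tagged_items(tsv, offset_base) else NULL
    ner_document(text, ents, doc_id = doc_id)
  })
}
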