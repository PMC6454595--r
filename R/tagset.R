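# Entity categories and the BIO tag set used throughout the package.

#' Entity categories
#'
#' The five clinical entity categories recognized by the tagger, in their
#' canonical (ASCII) spelling. Tagged-item files may use either these names or
#' the Chinese task labels returned by [category_labels()].
#'
#' @return Character vector of the five category identifiers.
#' @export
#' @examples
#' medner_categories()
medner_categories <- function() {
  c("anatomy", "surgery", "drug", "symptom_description", "independent_symptom")
}

# two-letter abbreviation used in BIO tags, keyed by category
category_abbrev <- function() {
  c(anatomy = "BO", surgery = "SU", drug = "DR",
    symptom_description = "SD", independent_symptom = "IS")
}

#' Default Chinese labels for the entity categories
#'
#' @return Named character vector mapping canonical category identifiers to
#'   the Chinese labels used in annotation files.
#' @export
category_labels <- function() {
  c(anatomy = "解剖部位",
    surgery = "手术",
    drug = "药物",
    symptom_description = "症状描述",
    independent_symptom = "独立症状")
}

#' The BIO tag set
#'
#' Eleven surface tags (one `O` plus a `B-`/`I-` pair per category), together
#' with the two reserved CRF states. The CRF transition matrix has dimension
#' `(k + 2) x (k + 2)` where `k` is the number of surface tags; the last two
#' indices are the START and STOP states, which never appear in emitted tag
#' sequences.
#'
#' @return A list with elements `labels` (character vector of length `k`),
#'   `k`, `start` and `stop` (1-based indices of the reserved states, i.e.
#'   `k + 1` and `k + 2`).
#' @export
#' @examples
#' ts <- medner_tags()
#' ts$k          # 11
#' ts$labels[1]  # "O"
medner_tags <- function() {
  ab <- category_abbrev()
  labels <- c("O",
              paste0("B-", ab["anatomy"]), paste0("I-", ab["anatomy"]),
              paste0("B-", ab["surgery"]), paste0("I-", ab["surgery"]),
              paste0("B-", ab["drug"]), paste0("I-", ab["drug"]),
              paste0("B-", ab["symptom_description"]), paste0("I-", ab["symptom_description"]),
              paste0("B-", ab["independent_symptom"]), paste0("I-", ab["independent_symptom"]))
  names(labels) <- NULL
  k <- length(labels)
  list(labels = labels, k = k, start = k + 1L, stop = k + 2L)
}

# tag label -> category, e.g. "B-BO" -> "anatomy"; "O" -> NA
tag_category <- function(tag) {
  ab <- category_abbrev()
  lut <- stats::setNames(names(ab), ab)
  out <- rep(NA_character_, length(tag))
  hit <- grepl("^[BI]-", tag)
  out[hit] <- lut[sub("^[BI]-", "", tag[hit])]
  out
}

# category -> B-/I- labels
bio_labels <- function(category, kind = c("B", "I")) {
  kind <- match.arg(kind)
  ab <- category_abbrev()
  paste0(kind, "-", ab[category])
}

normalize_category <- function(x) {
  cats <- medner_categories()
  zh <- category_labels()
  out <- character(length(x))
  for (i in seq_along(x)) {
    v <- x[i]
    if (v %in% cats) {
      out[i] <- v
    } else if (v %in% zh) {
      out[i] <- names(zh)[match(v, zh)]
    } else {
      stop("unknown entity category: '", v, "'", call. = FALSE)
    }
  }
  out
}
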