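# Shared fixture builders for the tests; everything is generated in code.

# a tiny hand-built document with two adjacent entities
abdomen_doc <- function() {
  ner_document("腹部不适。",
               entity_frame(c("腹部", "不适"), c(0L, 2L), c(2L, 4L),
                            c("anatomy", "symptom_description")),
               doc_id = "d1")
}

gold_predictions <- function(corpus) {
  preds <- lapply(corpus, function(d) d$entities)
  names(preds) <- vapply(corpus, function(d) d$doc_id, character(1))
  preds
}

# random well-formed document over a tiny inventory, for roundtrip tests
random_document <- function(doc_id = "r1") {
  n_sent <- sample(1:4, 1)
  text <- ""
  starts <- integer(0); ends <- integer(0); cats <- character(0)
  chars_ctx <- c("查", "体", "无", "明", "显")
  names_pool <- c("胃", "腹部", "卵巢切除术", "贝伐珠单抗", "发热", "压痛")
  cats_pool <- c("anatomy", "anatomy", "surgery", "drug",
                 "independent_symptom", "symptom_description")
  for (s in seq_len(n_sent)) {
    pre <- paste(sample(chars_ctx, sample(1:3, 1), replace = TRUE), collapse = "")
    i <- sample(length(names_pool), 1)
    nm <- names_pool[i]
    starts <- c(starts, nchar(text) + nchar(pre))
    ends <- c(ends, nchar(text) + nchar(pre) + nchar(nm))
    cats <- c(cats, cats_pool[i])
    text <- paste0(text, pre, nm,
                   paste(sample(chars_ctx, sample(0:2, 1), replace = TRUE), collapse = ""),
                   sample(c("。", "；", "！"), 1))
  }
  ner_document(text, entity_frame(substring(text, starts + 1, ends),
                                  starts, ends, cats), doc_id = doc_id)
}
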