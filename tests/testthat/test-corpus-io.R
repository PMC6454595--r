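test_that("tagged items parse, write and roundtrip", {
  e <- parse_tagged_item("胃\t12\t13\t解剖部位")
  expect_equal(e$name, "胃")
  expect_equal(e$start, 12L)
  expect_equal(e$end, 13L)
  expect_equal(e$category, "anatomy")
  # write(parse(line)) reproduces the line byte for byte
  line <- "贝伐珠单抗\t7\t12\t药物"
  expect_identical(write_tagged_items(parse_tagged_item(line)), line)
  # ASCII category aliases are accepted on read
  expect_equal(parse_tagged_item("胃\t12\t13\tanatomy")$category, "anatomy")
  # 1-based annotation files shift on read and back on write
  e1 <- parse_tagged_item("胃\t13\t14\t解剖部位", offset_base = 1)
  expect_equal(e1$start, 12L)
  expect_identical(write_tagged_items(e1, offset_base = 1), "胃\t13\t14\t解剖部位")
})

test_that("malformed tagged items are rejected with the offending line", {
  expect_error(parse_tagged_item("胃\t12\t13"), "4 tab-separated")
  expect_error(parse_tagged_item("胃\t12\t13\t解剖部位\tx"), "4 tab-separated")
  expect_error(parse_tagged_item("胃\ttwelve\t13\t解剖部位"), "integer")
  expect_error(parse_tagged_item("胃\t-1\t3\t解剖部位"), "integer")
  expect_error(parse_tagged_item("胃\t12\t13\t不明类别"), "unknown entity category")
})

test_that("tagged-item files roundtrip byte-identically", {
  withr::local_seed(42)
  dir <- withr::local_tempdir()
  for (i in 1:20) {
    doc <- random_document()
    f <- file.path(dir, "items.tsv")
    write_tagged_items(doc$entities, f)
    expect_identical(write_tagged_items(parse_tagged_items(f)),
                     write_tagged_items(doc$entities))
    raw1 <- readBin(f, "raw", file.size(f))
    write_tagged_items(parse_tagged_items(f), f)
    expect_identical(readBin(f, "raw", file.size(f)), raw1)
  }
})

test_that("sentence splitting keeps delimiters and covers the text", {
  sp <- split_sentences("腹痛。发热")
  expect_equal(unname(sp[, "start"]), c(0L, 3L))
  expect_equal(unname(sp[, "end"]), c(3L, 5L))
  expect_equal(nrow(split_sentences("")), 0L)
  one <- split_sentences("无分隔符文本")
  expect_equal(nrow(one), 1L)
  expect_equal(unname(one[1, ]), c(0L, 6L))
  # delimiters of every kind; concatenated spans reproduce the text
  txt <- "一。二；三！四？五\n六"
  sp <- split_sentences(txt)
  pieces <- substring(txt, sp[, "start"] + 1, sp[, "end"])
  expect_identical(paste(pieces, collapse = ""), txt)
  expect_true(all(sp[-1, "start"] == sp[-nrow(sp), "end"]))
})

test_that("BIO encoding matches the schema and decodes back", {
  doc <- abdomen_doc()
  tags <- encode_bio(doc)
  expect_equal(tags[[1]], c("B-BO", "I-BO", "B-SD", "I-SD", "O"))
  expect_equal(decode_bio(tags, doc), doc$entities)
  # no entities -> all O
  plain <- ner_document("查体无异常。")
  expect_true(all(unlist(encode_bio(plain)) == "O"))
  expect_equal(nrow(decode_bio(encode_bio(plain), plain)), 0L)
})

test_that("encode/decode are mutual inverses on random documents", {
  withr::local_seed(7)
  for (i in 1:50) {
    doc <- random_document()
    dec <- decode_bio(encode_bio(doc), doc)
    expect_equal(dec, doc$entities)
    expect_identical(dec$name, substring(doc$text, dec$start + 1, dec$end))
  }
})

test_that("overlapping entities are rejected, lenient I- decode warns", {
  expect_error(
    ner_document("腹部不适。", entity_frame(c("腹部不", "不适"), c(0L, 2L),
                                            c(3L, 4L), c("anatomy", "anatomy"))) |>
      encode_bio(),
    "overlapping"
  )
  doc <- ner_document("贝伐。")
  expect_warning(dec <- decode_bio(list(c("I-DR", "I-DR", "O")), doc),
                 "did not continue")
  expect_equal(dec, entity_frame("贝伐", 0L, 2L, "drug"))
  expect_error(decode_bio(list(c("B-XX", "O", "O")), doc), "unknown tag")
})

test_that("entities crossing a sentence split merge the sentences", {
  # entity spans the delimiter-adjacent boundary
  doc <- ner_document("查体腹部。不适明显。",
                      entity_frame("腹部。不适", 2L, 7L, "symptom_description"))
  expect_equal(nrow(doc$sentence_spans), 1L)
  expect_equal(decode_bio(encode_bio(doc), doc), doc$entities)
})

test_that("BIO column files roundtrip documents including escapes", {
  dir <- withr::local_tempdir()
  docs <- list(abdomen_doc(),
               ner_document("发热\n乏力。", entity_frame(c("发热", "乏力"),
                                                         c(0L, 3L), c(2L, 5L),
                                                         rep("independent_symptom", 2)),
                            doc_id = "d2"))
  f <- file.path(dir, "corpus.bio")
  write_bio(docs, f)
  back <- read_bio(f, doc_ids = c("d1", "d2"))
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_identical(back[[i]]$text, docs[[i]]$text)
    expect_equal(back[[i]]$entities, docs[[i]]$entities)
  }
})

test_that("corpus directories roundtrip text and annotations", {
  dir <- withr::local_tempdir()
  withr::local_seed(3)
  docs <- list(random_document("a1"), random_document("a2"))
  write_corpus(docs, dir)
  back <- read_corpus(dir)
  expect_equal(vapply(back, function(d) d$doc_id, ""), c("a1", "a2"))
  for (i in 1:2) {
    expect_identical(back[[i]]$text, docs[[i]]$text)
    expect_equal(back[[i]]$entities, docs[[i]]$entities)
  }
})

test_that("entity names must match the text slice", {
  expect_error(ner_document("腹部不适。", entity_frame("腹痛", 0L, 2L, "anatomy")),
               "does not match")
  expect_error(ner_document("腹部", entity_frame("腹部", 0L, 3L, "anatomy")),
               "invalid entity span")
})
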