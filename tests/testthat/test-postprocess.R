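correction_rows <- function() {
  list(list(wrong = "左附件", right = "左附件区", cat = "anatomy"),
       list(wrong = "卵巢切除", right = "卵巢切除术", cat = "surgery"),
       list(wrong = "贝伐", right = "贝伐珠单抗", cat = "drug"),
       list(wrong = "睡眠不佳", right = "饮食睡眠不佳", cat = "independent_symptom"),
       list(wrong = "疼痛", right = "疼痛不适", cat = "symptom_description"))
}

correction_base <- function() {
  rows <- correction_rows()
  medner:::entity_base(vapply(rows, `[[`, "", "right"),
                       vapply(rows, `[[`, "", "cat"))
}

test_that("the entity base tallies gold occurrences", {
  docs <- list(
    ner_document("胃。胃。", entity_frame(c("胃", "胃"), c(0L, 2L), c(1L, 3L),
                                          c("anatomy", "anatomy")), "d1"),
    ner_document("胃压痛。", entity_frame(c("胃", "压痛"), c(0L, 1L), c(1L, 3L),
                                          c("anatomy", "symptom_description")), "d2"))
  base <- build_entity_base(docs)
  expect_equal(base$occurrence[base$name == "胃"], 3L)
  expect_equal(sum(base$occurrence), 4L)   # conservation of gold mentions
  expect_equal(nrow(build_entity_base(list())), 0L)
  expect_error(medner:::entity_base(c("a", "a"), c("drug", "drug")), NA)
  expect_error(medner:::entity_base("a", "drug", 0L), "occurrence")
})

test_that("auto-correct restores boundaries from entity history", {
  base <- correction_base()
  # expansion to the full form present in the text
  text <- "查见左附件区肿大。"
  fix <- autocorrect_entity(entity_frame("左附件", 2L, 5L, "anatomy"), text, base)
  expect_equal(fix, entity_frame("左附件区", 2L, 6L, "anatomy"))
  # entity already in the base is trusted verbatim
  keep <- autocorrect_entity(entity_frame("左附件区", 2L, 6L, "anatomy"), text, base)
  expect_equal(keep$name, "左附件区")
  # window 0 is the identity
  expect_equal(autocorrect_entity(entity_frame("左附件", 2L, 5L, "anatomy"),
                                  text, base, window = 0L)$name, "左附件")
  # contraction of an over-extended span
  fix2 <- autocorrect_entity(entity_frame("左附件区肿", 2L, 7L, "anatomy"), text, base)
  expect_equal(fix2$name, "左附件区")
  # cross-category candidates require adopt_category
  textd <- "给予贝伐珠单抗。"
  ent <- entity_frame("贝伐", 2L, 4L, "anatomy")
  expect_equal(autocorrect_entity(ent, textd, base)$name, "贝伐")
  adopted <- autocorrect_entity(ent, textd, base, adopt_category = TRUE)
  expect_equal(adopted$name, "贝伐珠单抗")
  expect_equal(adopted$category, "drug")
})

test_that("auto-correct prefers occurrence, then span length, then leftmost", {
  text <- "体左附件区。"
  base <- medner:::entity_base(c("左附件", "左附件区"), c("anatomy", "anatomy"),
                               c(5L, 2L))
  ent <- entity_frame("附件", 2L, 4L, "anatomy")
  # higher occurrence wins over longer span
  expect_equal(autocorrect_entity(ent, text, base)$name, "左附件")
  base2 <- medner:::entity_base(c("左附件", "左附件区"), c("anatomy", "anatomy"),
                                c(3L, 3L))
  # tie on occurrence: longer span wins
  expect_equal(autocorrect_entity(ent, text, base2)$name, "左附件区")
})

test_that("drug dictionary matching is leftmost-longest", {
  m <- match_drugs("给予CPT-11治疗。", c("CPT", "CPT-11"))
  expect_equal(nrow(m), 1L)
  expect_equal(m$name, "CPT-11")
  expect_equal(m$category, "drug")
  expect_equal(nrow(match_drugs("任意文本", character(0))), 0L)
  # leftmost-longest suppresses overlaps
  expect_equal(match_drugs("ABC", c("AB", "BC"))$name, "AB")
  # ASCII entries match case-insensitively; CJK entries exactly
  expect_equal(match_drugs("给予cpt-11。", c("CPT-11"))$name, "cpt-11")
  # emitted matches never overlap and are maximal at their starts
  withr::local_seed(5)
  dict <- c("AB", "ABC", "BCD", "D", "贝伐", "贝伐珠单抗")
  for (i in 1:20) {
    text <- paste(sample(c("A", "B", "C", "D", "贝", "伐", "珠", "单", "抗", "。"),
                         30, replace = TRUE), collapse = "")
    m <- match_drugs(text, dict)
    if (nrow(m) > 1) {
      expect_true(all(m$start[-1] >= m$end[-nrow(m)]))
    }
    if (nrow(m) > 0) {
      expect_identical(m$name, substring(text, m$start + 1, m$end))
    }
  }
})

test_that("dictionary reconciliation rectifies, extracts and re-categorizes", {
  text <- "给予贝伐珠单抗与CPT-11。"
  dict <- c("贝伐珠单抗", "CPT", "CPT-11")
  matches <- match_drugs(text, dict)
  # boundary rectification: overlapping prediction is replaced by the match
  pred <- entity_frame("贝伐", 2L, 4L, "drug")
  out <- merge_drug_entities(pred, matches)
  expect_true(any(out$name == "贝伐珠单抗"))
  expect_false(any(out$name == "贝伐"))
  # extraction: matches with no overlapping prediction are added
  expect_true(any(out$name == "CPT-11"))
  # no matches: predictions unchanged
  expect_equal(merge_drug_entities(pred, medner:::empty_entities()), pred)
  # exact-span non-drug predictions are re-categorized
  pred2 <- entity_frame("贝伐珠单抗", 2L, 7L, "anatomy")
  out2 <- merge_drug_entities(pred2, matches)
  expect_equal(out2$category[out2$name == "贝伐珠单抗"], "drug")
})

test_that("boundary rules strip, merge and extract as specified", {
  base <- medner:::entity_base(c("附件区", "胃"), c("anatomy", "anatomy"))
  # rule 6: trailing 旁 is stripped from anatomy
  text <- "见胃旁。"
  out <- apply_rules(entity_frame("胃旁", 1L, 3L, "anatomy"), text)
  expect_equal(out, entity_frame("胃", 1L, 2L, "anatomy"))
  # rule 7: orientation prefix merges into anatomy
  text2 <- "见左附件区。"
  out2 <- apply_rules(entity_frame("附件区", 2L, 5L, "anatomy"), text2)
  expect_equal(out2$name, "左附件区")
  # rule 8: orientation suffix merges into anatomy
  text3 <- "见胃周。"
  out3 <- apply_rules(entity_frame("胃", 1L, 2L, "anatomy"), text3)
  expect_equal(out3$name, "胃周")
  # rule 9: trailing 术 / 手术 merges into surgery
  text4 <- "行卵巢切除术。"
  out4 <- apply_rules(entity_frame("卵巢切除", 1L, 5L, "surgery"), text4)
  expect_equal(out4$name, "卵巢切除术")
  # rules do not fire across categories
  out5 <- apply_rules(entity_frame("胃", 1L, 2L, "drug"), text3)
  expect_equal(out5$name, "胃")
  # gazetteer extraction adds missed anatomy/surgery names only
  text6 <- "见附件区又见胃。"
  out6 <- apply_rules(medner:::empty_entities(), text6, base = base)
  expect_equal(out6$name, c("附件区", "胃"))
  expect_equal(out6$category, c("anatomy", "anatomy"))
  # extraction never overlaps an existing prediction
  out7 <- apply_rules(entity_frame("附件区", 1L, 4L, "anatomy"), text6, base = base)
  expect_equal(nrow(out7), 2L)
})

test_that("rules files roundtrip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  write_rules(default_rules(), f)
  back <- read_rules(f)
  expect_equal(back, default_rules())
  writeLines("- kind: strip_suffix\n  category: anatomy\n  tokens: []", f)
  expect_error(read_rules(f), "non-empty token list")
})

test_that("entity base and drug dictionary files roundtrip", {
  dir <- withr::local_tempdir()
  base <- correction_base()
  f <- file.path(dir, "base.tsv")
  write_entity_base(base, f)
  expect_equal(read_entity_base(f), base)
  d <- file.path(dir, "drugs.txt")
  writeLines(c("# 注释", "CPT-11", "", "贝伐珠单抗"), d)
  expect_equal(read_drug_dictionary(d), c("CPT-11", "贝伐珠单抗"))
})

test_that("the pipeline maps every recognized form to its correct form", {
  base <- correction_base()
  dict <- c("贝伐珠单抗", "CPT", "CPT-11")
  for (r in correction_rows()) {
    text <- paste0("患者见", r$right, "。")
    s <- 3L + as.integer(regexpr(r$wrong, r$right, fixed = TRUE)) - 1L
    pred <- entity_frame(r$wrong, s, s + nchar(r$wrong), r$cat)
    out <- postprocess_entities(pred, text, base = base, dict = dict)
    expect_equal(nrow(out), 1L, label = r$wrong)
    expect_equal(out$name, r$right)
    expect_equal(out$category, r$cat)
    expect_identical(out$name, substring(text, out$start + 1, out$end))
  }
})

test_that("the pipeline is idempotent and empty components are no-ops", {
  synth <- generate_corpus(generator_config(n_docs = 15, seed = 77))
  preds <- gold_predictions(synth$documents)
  # all components absent: identity
  same <- postprocess_corpus(preds, synth$documents, base = NULL, dict = NULL,
                             rules = NULL)
  expect_equal(same, preds)
  run <- function(p, order = c("autocorrect", "dictionary", "rules")) {
    postprocess_corpus(p, synth$documents, base = synth$entity_base,
                       dict = synth$drug_dictionary, rules = default_rules(),
                       order = order)
  }
  noise <- generate_boundary_noise(synth, 0.4, seed = 5)
  once <- run(noise$predictions)
  expect_identical(run(once), once)
  # each order is individually idempotent
  alt <- c("rules", "dictionary", "autocorrect")
  once_alt <- run(noise$predictions, alt)
  expect_identical(run(once_alt, alt), once_alt)
  # every output entity matches its text slice
  for (i in seq_along(synth$documents)) {
    o <- once[[synth$documents[[i]]$doc_id]]
    expect_identical(o$name,
                     substring(synth$documents[[i]]$text, o$start + 1, o$end))
  }
})
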