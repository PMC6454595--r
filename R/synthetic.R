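# Seeded generator of synthetic EMR-like documents with gold annotations.
#
# The generated corpora exhibit the statistical structure the tagger and the
# auxiliary measures assume: five entity categories placed in category-cued
# sentence templates, repeated mentions that may be emitted in truncated
# (abbreviated) form, boundary-rule trigger contexts (orientation prefixes
# and suffixes, trailing 旁), and companion entity-base / drug-dictionary
# fixtures tallying the full forms. Cue characters are disjoint from entity
# characters, so entity category is a deterministic function of the local
# context and a correct tagger can learn the corpus to near-perfect
# held-out F1; see the methods vignette for what this does and does not
# show about real clinical text.

synth_gazetteers <- function() {
  list(
    anatomy = c("胃", "腹部", "肝脏", "胆囊", "脾脏", "结肠", "直肠", "膀胱",
                "卵巢", "盆腔", "附件区", "左附件区", "食管", "甲状腺", "乳腺",
                "淋巴结", "肾脏", "胰腺"),
    surgery = c("卵巢切除术", "胃切除术", "胆囊切除术", "阑尾切除术",
                "子宫切除术", "结肠造瘘术", "肿物穿刺术", "淋巴结清扫术",
                "引流术", "吻合术", "修补术", "脾切除术"),
    drug = c("贝伐珠单抗", "奥沙利铂", "卡培他滨", "紫杉醇", "顺铂",
             "氟尿嘧啶", "吉西他滨", "依托泊苷", "多西他赛", "环磷酰胺",
             "表柔比星", "CPT-11", "CPT", "5-FU"),
    independent_symptom = c("饮食睡眠不佳", "发热", "恶心呕吐", "乏力", "头晕",
                            "腹泻", "便秘", "心悸", "畏寒", "盗汗", "咳嗽咳痰"),
    symptom_description = c("疼痛不适", "压痛", "反跳痛", "隐痛", "胀痛",
                            "肿大", "增厚", "酸胀", "钝痛", "灼痛", "刺痛")
  )
}

synth_templates <- function() {
  list(
    anatomy = list(c("查体见", "正常。"), c("患者", "无异样。"), c("今日复诊", "情况可。")),
    surgery = list(c("入院后行", "。"), c("患者接受", "治疗好转。"), c("期间行", "过程良好。")),
    drug = list(c("给予", "静滴。"), c("开始服用", "。"), c("予以", "化疗。")),
    independent_symptom = list(c("患者自诉", "数天。"), c("近日出现", "。"), c("伴有", "多日。")),
    symptom_description = list(c("可触及", "。"), c("按压时", "加重。"), c("触诊有", "明显。"))
  )
}

synth_neutral <- function() c("一般情况良好。", "继续观察。", "无特殊。")

#' Configuration for the synthetic corpus generator
#'
#' @param n_docs Number of documents.
#' @param sentences_per_doc Integer range `c(min, max)` of entity-bearing
#'   sentences per document.
#' @param abbreviation_rate Probability that a document's repeated mention is
#'   emitted in truncated (abbreviated) form rather than repeated verbatim.
#' @param rule_trigger_rate Fraction of anatomy mentions wrapped in a
#'   boundary-rule context (orientation prefix or suffix absorbed into the
#'   gold span, or a trailing 旁 left outside it).
#' @param seed Master seed; each document derives its own RNG stream from
#'   `(seed, doc index)`, so corpora are stable under changes of `n_docs`.
#' @param gazetteers,templates Name lists per category and sentence
#'   templates; defaults ship with the package.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_docs = 50L, sentences_per_doc = c(4L, 8L),
                             abbreviation_rate = 0.3, rule_trigger_rate = 0.2,
                             seed = 1L, gazetteers = synth_gazetteers(),
                             templates = synth_templates()) {
  if (abbreviation_rate < 0 || abbreviation_rate > 1 ||
      rule_trigger_rate < 0 || rule_trigger_rate > 1) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (n_docs < 0) stop("n_docs must be non-negative", call. = FALSE)
  missing_cat <- setdiff(medner_categories(), names(gazetteers))
  if (length(missing_cat) || any(lengths(gazetteers[medner_categories()]) == 0)) {
    stop("gazetteers must be non-empty for all five categories", call. = FALSE)
  }
  structure(list(n_docs = as.integer(n_docs),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 abbreviation_rate = abbreviation_rate,
                 rule_trigger_rate = rule_trigger_rate,
                 seed = as.integer(seed), gazetteers = gazetteers,
                 templates = templates),
            class = "generator_config")
}

is_cjk <- function(x) !is_ascii(x)

truncate_mention <- function(name, drop) {
  substring(name, 1L, n_chars(name) - drop)
}

# one synthetic document under its own RNG stream
synth_document <- function(config, i) {
  gaz <- config$gazetteers
  tpl <- config$templates
  cats <- medner_categories()
  force_trunc <- i == 1L && config$abbreviation_rate > 0
  with_seed(derive_seed(config$seed, i), {
    n_range <- seq(config$sentences_per_doc[1], config$sentences_per_doc[2])
    n_sent <- n_range[sample.int(length(n_range), 1L)]
    text <- ""
    log <- list()
    add_log <- function(start, end, name, category, full_form, kind) {
      log[[length(log) + 1L]] <<- data.frame(
        start = start, end = end, name = name, category = category,
        full_form = full_form, kind = kind, stringsAsFactors = FALSE)
    }
    for (s in seq_len(n_sent)) {
      if (stats::runif(1) < 0.15) {
        text <- paste0(text, sample(synth_neutral(), 1L))
        next
      }
      # deterministic category coverage: sentence 1 of document i always
      # carries category ((i - 1) mod 5) + 1
      ct <- if (s == 1L) cats[(i - 1L) %% 5L + 1L] else sample(cats, 1L)
      nm <- sample(gaz[[ct]], 1L)
      parts <- tpl[[ct]][[sample(length(tpl[[ct]]), 1L)]]
      pre <- parts[1]; post <- parts[2]
      kind <- "plain"
      gold_name <- nm
      if (ct == "anatomy" && stats::runif(1) < config$rule_trigger_rate) {
        kind <- sample(c("orient_prefix", "orient_suffix", "side_context"), 1L)
        if (kind == "orient_prefix") {
          gold_name <- paste0(sample(c("右上", "左上", "右", "左"), 1L), nm)
        } else if (kind == "orient_suffix") {
          gold_name <- paste0(nm, sample(c("周", "上", "下", "外"), 1L))
        } else {
          post <- paste0("旁", post)   # 旁 follows the entity, outside the span
        }
      }
      start <- n_chars(text) + n_chars(pre)
      end <- start + n_chars(gold_name)
      add_log(start, end, gold_name, ct, gold_name, kind)
      text <- paste0(text, pre, gold_name, post)
    }
    # one repeated mention per document, possibly truncated
    ents <- if (length(log)) do.call(rbind, log) else NULL
    if (!is.null(ents)) {
      cand <- which(ents$kind == "plain" & is_cjk(ents$full_form) &
                      nchar(ents$full_form, type = "chars") >= 3L)
      if (length(cand)) {
        # index into cand explicitly: sample(x, 1) on a length-one vector
        # would draw from 1:x instead
        pick <- ents[cand[sample.int(length(cand), 1L)], ]
        truncated <- force_trunc || stats::runif(1) < config$abbreviation_rate
        form <- if (truncated) {
          len <- n_chars(pick$full_form)
          truncate_mention(pick$full_form, if (len >= 5L) sample(1:2, 1L) else 1L)
        } else pick$full_form
        start <- n_chars(text) + 2L   # after the cue 复查
        add_log(start, start + n_chars(form), form, pick$category,
                pick$full_form, if (truncated) "abbreviation" else "repeat")
        text <- paste0(text, "复查", form, "同前。")
      }
    }
    log_df <- if (length(log)) do.call(rbind, log) else
      data.frame(start = integer(), end = integer(), name = character(),
                 category = character(), full_form = character(),
                 kind = character(), stringsAsFactors = FALSE)
    doc_id <- sprintf("synth%04d", i)
    log_df$doc_id <- rep(doc_id, nrow(log_df))
    doc <- ner_document(text, entity_frame(log_df$name, log_df$start,
                                           log_df$end, log_df$category),
                        doc_id = doc_id)
    list(doc = doc, log = log_df)
  })
}

#' Generate a synthetic annotated corpus
#'
#' Deterministic given the config seed. Returns the documents together with
#' companion fixtures: an entity base tallying every mention under its full
#' form (so boundary auto-correction can restore truncations), the drug
#' dictionary (the drug gazetteer, including the `CPT`/`CPT-11` inclusion
#' pair), and a generation log recording each mention's full form and any
#' rule-trigger context.
#'
#' @param config A [generator_config()].
#' @return A list of class `medner_synth` with elements `documents`,
#'   `entity_base`, `drug_dictionary`, `log`.
#' @export
#' @examples
#' synth <- generate_corpus(generator_config(n_docs = 3, seed = 42))
#' length(synth$documents)
generate_corpus <- function(config = generator_config()) {
  if (!inherits(config, "generator_config")) {
    stop("config must be a generator_config()", call. = FALSE)
  }
  out <- lapply(seq_len(config$n_docs), function(i) synth_document(config, i))
  docs <- lapply(out, `[[`, "doc")
  log <- do.call(rbind, c(list(data.frame(start = integer(), end = integer(),
                                          name = character(), category = character(),
                                          full_form = character(), kind = character(),
                                          doc_id = character(),
                                          stringsAsFactors = FALSE)),
                          lapply(out, `[[`, "log")))
  base <- if (nrow(log)) entity_base(log$full_form, log$category) else
    entity_base(character(), character())
  structure(list(documents = docs, entity_base = base,
                 drug_dictionary = config$gazetteers$drug, log = log),
            class = "medner_synth")
}

#' @export
print.medner_synth <- function(x, ...) {
  cat("<synthetic corpus: ", length(x$documents), " documents, ",
      nrow(x$log), " gold mentions, entity base of ", nrow(x$entity_base),
      " full forms>\n", sep = "")
  invisible(x)
}

#' Manufacture boundary-noisy predictions from gold annotations
#'
#' Copies the gold entities and perturbs a seeded fraction of them by
#' truncating or extending a boundary by 1-2 characters, the error mode the
#' auto-correct window (default 3) can reach. Only mentions whose surface
#' form is a full form present in the companion entity base are perturbed
#' (recovery is measured by restoring the full form). The intended
#' correction is recorded for scoring.
#'
#' @param synth A [generate_corpus()] result.
#' @param noise_rate Fraction of eligible entities to perturb.
#' @param seed Seed (per-document streams derived as in the generator).
#' @return A list with `predictions` (named list of entity data frames) and
#'   `log` (data frame with the original and perturbed spans and a
#'   `perturbed` flag).
#' @export
generate_boundary_noise <- function(synth, noise_rate = 0.3, seed = 1L) {
  if (noise_rate < 0 || noise_rate > 1) stop("noise_rate must be in [0, 1]", call. = FALSE)
  base_names <- synth$entity_base$name
  preds <- list(); logs <- list()
  for (i in seq_along(synth$documents)) {
    doc <- synth$documents[[i]]
    ents <- doc$entities
    n_doc <- n_chars(doc$text)
    log <- data.frame(doc_id = rep(doc$doc_id, nrow(ents)),
                      orig_start = ents$start, orig_end = ents$end,
                      category = ents$category,
                      start = ents$start, end = ents$end,
                      perturbed = rep(FALSE, nrow(ents)),
                      stringsAsFactors = FALSE)
    with_seed(derive_seed(seed, i) + 17, {
      for (j in seq_len(nrow(ents))) {
        if (!(ents$name[j] %in% base_names)) next
        if (stats::runif(1) >= noise_rate) next
        len <- ents$end[j] - ents$start[j]
        moves <- list()
        for (amt in 1:2) {
          if (len - amt >= 1L) {
            moves <- c(moves, list(c(amt, 0L), c(0L, -amt)))   # truncate left/right
          }
          if (ents$start[j] - amt >= 0L) moves <- c(moves, list(c(-amt, 0L)))
          if (ents$end[j] + amt <= n_doc) moves <- c(moves, list(c(0L, amt)))
        }
        if (!length(moves)) next
        mv <- moves[[sample(length(moves), 1L)]]
        log$start[j] <- ents$start[j] + mv[1]
        log$end[j] <- ents$end[j] + mv[2]
        log$perturbed[j] <- TRUE
      }
    })
    preds[[doc$doc_id]] <- entity_frame(slice_text(doc$text, log$start, log$end),
                                        log$start, log$end, log$category)
    logs[[i]] <- log
  }
  list(predictions = preds, log = do.call(rbind, logs))
}

#' Fraction of perturbed entities restored by post-processing
#'
#' @param postprocessed Named list of post-processed entity data frames.
#' @param noise_log The `log` component of [generate_boundary_noise()].
#' @return Fraction of perturbed entities whose original
#'   `(start, end, category)` triple is present in the post-processed
#'   output (1 if nothing was perturbed).
#' @export
recovery_rate <- function(postprocessed, noise_log) {
  pert <- noise_log[noise_log$perturbed, , drop = FALSE]
  if (!nrow(pert)) return(1)
  ok <- vapply(seq_len(nrow(pert)), function(r) {
    ents <- postprocessed[[pert$doc_id[r]]]
    any(ents$start == pert$orig_start[r] & ents$end == pert$orig_end[r] &
          ents$category == pert$category[r])
  }, logical(1))
  mean(ok)
}
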