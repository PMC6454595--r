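# Correctness of the neural tagger: analytic gradients against finite
# differences, the document loss against the enumeration oracle, training
# determinism and descent, and prediction as Viterbi + BIO decode.

tiny_params <- function(variant, d = 3L, h = 2L, V = 6L, seed = 2L) {
  k <- medner_tags()$k
  emb <- medner:::with_seed(seed, matrix(rnorm(V * d, sd = 0.3), V, d))
  p <- medner:::with_seed(seed + 1, medner:::init_params(emb, d, h, k, variant))
  medner:::with_seed(seed + 2, lapply(p, function(x) x + rnorm(length(x), sd = 0.05)))
}

test_that("backpropagation matches finite differences for both variants", {
  withr::local_seed(17)
  sents <- list(c(1L, 3L, 5L), c(2L, 6L))
  gold <- list(c(1L, 2L, 3L), c(4L, 1L))
  for (variant in c("bilstm_crf", "attention_bilstm_crf")) {
    params <- tiny_params(variant)
    res <- medner:::unit_loss_grad(params, variant, sents, gold,
                                   dropout = 0, training = FALSE)
    lossfn <- function(pp) {
      medner:::unit_loss_grad(pp, variant, sents, gold,
                              dropout = 0, training = FALSE)$nll
    }
    eps <- 1e-5
    for (nm in names(params)) {
      g <- res$grads[[nm]]
      for (ii in sample(length(g), min(6, length(g)))) {
        p1 <- params; p1[[nm]][ii] <- p1[[nm]][ii] + eps
        p2 <- params; p2[[nm]][ii] <- p2[[nm]][ii] - eps
        num <- (lossfn(p1) - lossfn(p2)) / (2 * eps)
        expect_equal(g[ii], num, tolerance = 1e-3,
                     label = paste(variant, nm, "grad entry"))
      }
    }
  }
})

test_that("document loss equals the per-sentence enumeration oracle", {
  # frozen weights, tiny 2-sentence document; oracle enumerates all paths
  withr::local_seed(23)
  sents <- list(c(1L, 4L), c(3L, 2L, 5L))
  gold <- list(c(2L, 7L), c(1L, 11L, 4L))
  for (variant in c("bilstm_crf", "attention_bilstm_crf")) {
    params <- tiny_params(variant)
    fw <- medner:::unit_forward(params, variant, sents, training = FALSE)
    oracle <- 0
    for (s in seq_along(sents)) {
      P <- fw$P[fw$rows[[s]], , drop = FALSE]
      scores <- oracle_all_scores(P, params$A)
      oracle <- oracle - (oracle_path_score(P, params$A, gold[[s]]) -
                            (max(scores) + log(sum(exp(scores - max(scores))))))
    }
    res <- medner:::unit_loss_grad(params, variant, sents, gold,
                                   dropout = 0, training = FALSE)
    expect_equal(res$nll, oracle, tolerance = 1e-8)
    expect_gte(res$nll, 0)
  }
})

test_that("uniform attention context degenerates to averaged encoder states", {
  # with W frozen at 0 every pairwise score ties, so each G row must be the
  # column mean of H and the attention matrix is exactly uniform
  withr::local_seed(29)
  params <- tiny_params("attention_bilstm_crf")
  params$Watt <- matrix(0, 3, 3)
  sents <- list(c(1L, 2L), c(3L, 4L, 5L))
  fw <- medner:::unit_forward(params, "attention_bilstm_crf", sents, training = FALSE)
  N <- nrow(fw$H)
  expect_equal(fw$A_att[[1]], matrix(1 / N, N, N), ignore_attr = TRUE)
  for (i in seq_len(N)) expect_equal(unname(fw$G[i, ]), unname(colMeans(fw$H)))
})

test_that("prediction composes Viterbi decoding with BIO decoding", {
  withr::local_seed(37)
  synth <- generate_corpus(generator_config(n_docs = 2, seed = 3))
  model <- medner(synth$documents, variant = "bilstm_crf",
                  control = medner_control(dim = 8, hidden = 6, epochs = 1,
                                           dropout = 0, seed = 5))
  doc <- synth$documents[[1]]
  pred <- suppressWarnings(predict(model, list(doc))[[1]])
  # recompute by hand from the model internals
  spans <- doc$sentence_spans
  sents <- lapply(seq_len(nrow(spans)), function(j) {
    chars <- substring(doc$text, spans[j, 1] + 1, spans[j, 2]) |>
      strsplit("") |> unlist()
    medner:::tokens_to_ids(chars, model$vocab)
  })
  fw <- medner:::unit_forward(model$params, model$variant, sents, training = FALSE)
  tag_seqs <- lapply(seq_along(fw$rows), function(s) {
    model$tags$labels[crf_viterbi(fw$P[fw$rows[[s]], , drop = FALSE],
                                  model$params$A)$path]
  })
  expect_equal(pred, suppressWarnings(decode_bio(tag_seqs, doc)))
  # empty document -> no entities
  expect_equal(nrow(predict(model, list(ner_document("")))[[1]]), 0L)
})

test_that("training is seed-deterministic and loss descends", {
  synth <- generate_corpus(generator_config(n_docs = 10, seed = 19))
  ctl <- medner_control(dim = 16, hidden = 12, epochs = 6, seed = 7)
  m1 <- medner(synth$documents, variant = "bilstm_crf", control = ctl)
  m2 <- medner(synth$documents, variant = "bilstm_crf", control = ctl)
  expect_identical(m1$loss_history[1], m2$loss_history[1])
  expect_identical(m1$params, m2$params)
  expect_lte(m1$loss_history[6], m1$loss_history[1])
  expect_error(medner(list(), variant = "bilstm_crf"), "empty")
})

test_that("a small model memorizes its training corpus", {
  # unambiguous lexical cues: 50 documents, 10 epochs suffice
  synth <- generate_corpus(generator_config(n_docs = 50, seed = 41,
                                            abbreviation_rate = 0))
  model <- medner(synth$documents, variant = "bilstm_crf",
                  control = medner_control(dim = 32, hidden = 32, epochs = 10,
                                           dropout = 0.1, seed = 13))
  preds <- suppressWarnings(predict(model, synth$documents))
  sc <- strict_prf(synth$documents, preds)
  expect_gte(sc$f1[sc$category == "total"], 0.99)
  # document loss of a memorized document is small
  expect_lt(medner_loss(model, synth$documents[[1]]),
            5 * length(encode_bio(synth$documents[[1]])))
})

test_that("checkpoints roundtrip and refuse foreign versions", {
  synth <- generate_corpus(generator_config(n_docs = 2, seed = 3))
  model <- medner(synth$documents, variant = "bilstm_crf",
                  control = medner_control(dim = 6, hidden = 4, epochs = 1, seed = 5))
  f <- withr::local_tempfile(fileext = ".rds")
  save_medner(model, f)
  back <- read_medner(f)
  expect_identical(back$params, model$params)
  expect_identical(suppressWarnings(predict(back, synth$documents)),
                   suppressWarnings(predict(model, synth$documents)))
  saveRDS(list(format_version = 99L, model = unclass(model)), f)
  expect_error(read_medner(f), "format version")
})

test_that("control validation and summary methods behave", {
  expect_error(medner_control(epochs = 0), "epochs")
  expect_error(medner_control(dropout = 1), "dropout")
  synth <- generate_corpus(generator_config(n_docs = 2, seed = 3))
  model <- medner(synth$documents, variant = "bilstm_crf",
                  control = medner_control(dim = 6, hidden = 4, epochs = 2, seed = 5))
  expect_output(print(model), "bilstm_crf")
  expect_output(print(summary(model)), "parameters")
  expect_true(is.matrix(coef(model)$transitions))
  expect_s3_class(logLik(model), "logLik")
})
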