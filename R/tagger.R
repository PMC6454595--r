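# The sequence tagger: character embeddings -> per-sentence BiLSTM ->
# (optionally) document-level attention -> linear-chain CRF. Trained with
# Adam at batch size one on the negative CRF log-likelihood; all gradients
# are computed analytically in this file and checked against finite
# differences in the test suite.

#' Tagger hyperparameters
#'
#' @param dim Embedding dimension `d`.
#' @param hidden Hidden units per LSTM direction (the concatenated state has
#'   `2 * hidden` coordinates).
#' @param dropout Inverted-dropout rate on the look-up layer, in `[0, 1)`.
#' @param epochs Training epochs (default 45).
#' @param learning_rate Adam step size.
#' @param clip Global gradient-norm clip.
#' @param seed Seed controlling initialization, dropout and shuffling.
#' @param max_doc_tokens Attention window cap: documents longer than this
#'   (in tokens) are split into non-overlapping attention blocks at sentence
#'   boundaries. Default unlimited.
#' @param forbid_invalid_transitions If `TRUE`, Viterbi decoding masks tag
#'   transitions that violate the BIO schema. Default `FALSE`.
#' @return A list of class `medner_control`.
#' @export
medner_control <- function(dim = 100L, hidden = 100L, dropout = 0.5,
                           epochs = 45L, learning_rate = 1e-3, clip = 5,
                           seed = 1L, max_doc_tokens = Inf,
                           forbid_invalid_transitions = FALSE) {
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)", call. = FALSE)
  structure(list(dim = as.integer(dim), hidden = as.integer(hidden),
                 dropout = dropout, epochs = as.integer(epochs),
                 learning_rate = learning_rate, clip = clip,
                 seed = as.integer(seed), max_doc_tokens = max_doc_tokens,
                 forbid_invalid_transitions = isTRUE(forbid_invalid_transitions)),
            class = "medner_control")
}

init_params <- function(emb_matrix, d, hsz, k, variant) {
  u <- function(nr, nc, r = 0.1) matrix(stats::runif(nr * nc, -r, r), nr, nc)
  m2 <- 2L * hsz
  b0 <- numeric(4L * hsz)
  b0[hsz + seq_len(hsz)] <- 1            # forget-gate bias
  p <- list(emb = emb_matrix,
            f_Wx = u(4L * hsz, d), f_Wh = u(4L * hsz, hsz), f_b = b0,
            b_Wx = u(4L * hsz, d), b_Wh = u(4L * hsz, hsz), b_b = b0,
            A = u(k + 2L, k + 2L))
  if (variant == "bilstm_crf") {
    p$Wo <- u(m2, k); p$bo <- numeric(k)
  } else {
    # W = -I at initialization: attention starts as a similarity kernel
    # (exp of negative squared distance) and is free to move away
    p$Watt <- -diag(d)
    p$Wz <- u(2L * m2, k); p$bz <- numeric(k)
  }
  p
}

zero_grads <- function(params) lapply(params, function(x) x * 0)

sentence_blocks <- function(lens, max_tokens) {
  if (!is.finite(max_tokens) || sum(lens) <= max_tokens) {
    return(list(seq_along(lens)))
  }
  blocks <- list(); cur <- integer(0); tot <- 0
  for (s in seq_along(lens)) {
    if (length(cur) && tot + lens[s] > max_tokens) {
      blocks[[length(blocks) + 1L]] <- cur; cur <- integer(0); tot <- 0
    }
    cur <- c(cur, s); tot <- tot + lens[s]
  }
  blocks[[length(blocks) + 1L]] <- cur
  blocks
}

# Forward pass over one unit (a list of token-id sentences forming a
# document for the attention variant, or a single sentence for the
# baseline). Returns emissions and every cache needed for the backward pass.
unit_forward <- function(params, variant, sents, dropout = 0, training = FALSE,
                         max_doc_tokens = Inf) {
  lens <- lengths(sents)
  keep <- lens > 0L
  sents <- sents[keep]; lens <- lens[keep]
  if (!length(sents)) return(NULL)
  ids <- unlist(sents, use.names = FALSE)
  N <- length(ids)
  emb <- embed_sequence(ids, list(matrix = params$emb), dropout, training)
  X <- emb$X
  ends <- cumsum(lens)
  rows <- lapply(seq_along(lens), function(s) (c(0L, ends)[s] + 1L):ends[s])
  fwd <- list(Wx = params$f_Wx, Wh = params$f_Wh, b = params$f_b)
  bwd <- list(Wx = params$b_Wx, Wh = params$b_Wh, b = params$b_b)
  encs <- vector("list", length(sents))
  hsz <- ncol(params$f_Wh)
  H <- matrix(0, N, 2L * hsz)
  for (s in seq_along(sents)) {
    encs[[s]] <- bilstm_sentence(X[rows[[s]], , drop = FALSE], fwd, bwd)
    H[rows[[s]], ] <- encs[[s]]$H
  }
  out <- list(ids = ids, X = X, mask = emb$mask, rows = rows, H = H,
              encs = encs, lens = lens)
  if (variant == "bilstm_crf") {
    out$P <- H %*% params$Wo + rep(params$bo, each = N)
  } else {
    blocks <- sentence_blocks(lens, max_doc_tokens)
    out$blocks <- lapply(blocks, function(bs) unlist(rows[bs], use.names = FALSE))
    out$A_att <- vector("list", length(out$blocks))
    G <- matrix(0, N, 2L * hsz)
    for (bi in seq_along(out$blocks)) {
      br <- out$blocks[[bi]]
      Ab <- attention_matrix(X[br, , drop = FALSE], params$Watt)
      out$A_att[[bi]] <- Ab
      G[br, ] <- Ab %*% H[br, , drop = FALSE]
    }
    out$G <- G
    out$Z <- cbind(G, H)
    # tanh squashes the concatenated [G; H] vector; an affine map then
    # produces the k emission scores the CRF consumes
    out$TZ <- tanh(out$Z)
    out$P <- out$TZ %*% params$Wz + rep(params$bz, each = N)
  }
  out
}

# Loss and analytic gradients for one unit. gold is a list of integer tag
# paths aligned with the (non-empty) sentences.
unit_loss_grad <- function(params, variant, sents, gold, dropout = 0,
                           training = TRUE, max_doc_tokens = Inf) {
  gold <- gold[lengths(sents) > 0L]
  fw <- unit_forward(params, variant, sents, dropout, training, max_doc_tokens)
  if (is.null(fw)) return(NULL)
  k <- ncol(params$A) - 2L
  N <- nrow(fw$P)
  nll <- 0
  dP <- matrix(0, N, k)
  grads <- zero_grads(params)
  for (s in seq_along(fw$rows)) {
    res <- crf_nll_grad(fw$P[fw$rows[[s]], , drop = FALSE], params$A, gold[[s]])
    nll <- nll + res$nll
    dP[fw$rows[[s]], ] <- res$dP
    grads$A <- grads$A + res$dA
  }
  hsz <- ncol(params$f_Wh)
  m2 <- 2L * hsz
  if (variant == "bilstm_crf") {
    dH <- dP %*% t(params$Wo)
    grads$Wo <- crossprod(fw$H, dP)
    grads$bo <- colSums(dP)
    dX_att <- NULL
  } else {
    grads$Wz <- crossprod(fw$TZ, dP)
    grads$bz <- colSums(dP)
    dZ <- (dP %*% t(params$Wz)) * (1 - fw$TZ^2)
    dG <- dZ[, seq_len(m2), drop = FALSE]
    dH <- dZ[, m2 + seq_len(m2), drop = FALSE]
    dX_att <- matrix(0, N, ncol(fw$X))
    M <- params$Watt + t(params$Watt)
    for (bi in seq_along(fw$blocks)) {
      br <- fw$blocks[[bi]]
      Ab <- fw$A_att[[bi]]
      Hb <- fw$H[br, , drop = FALSE]
      dGb <- dG[br, , drop = FALSE]
      dH[br, ] <- dH[br, , drop = FALSE] + crossprod(Ab, dGb)
      dAb <- tcrossprod(dGb, Hb)
      dS <- Ab * (dAb - rowSums(dAb * Ab))
      Xb <- fw$X[br, , drop = FALSE]
      inner <- Xb * (rowSums(dS) + colSums(dS)) - (dS + t(dS)) %*% Xb
      grads$Watt <- grads$Watt + crossprod(Xb, inner)
      dX_att[br, ] <- inner %*% M
    }
  }
  fwd <- list(Wx = params$f_Wx, Wh = params$f_Wh, b = params$f_b)
  bwd <- list(Wx = params$b_Wx, Wh = params$b_Wh, b = params$b_b)
  dX <- matrix(0, N, ncol(fw$X))
  for (s in seq_along(fw$rows)) {
    rs <- fw$rows[[s]]
    g <- bilstm_sentence_backward(fw$encs[[s]], fw$X[rs, , drop = FALSE],
                                  fwd, bwd, dH[rs, , drop = FALSE])
    grads$f_Wx <- grads$f_Wx + g$fwd$dWx
    grads$f_Wh <- grads$f_Wh + g$fwd$dWh
    grads$f_b <- grads$f_b + g$fwd$db
    grads$b_Wx <- grads$b_Wx + g$bwd$dWx
    grads$b_Wh <- grads$b_Wh + g$bwd$dWh
    grads$b_b <- grads$b_b + g$bwd$db
    dX[rs, ] <- g$dX
  }
  if (!is.null(dX_att)) dX <- dX + dX_att
  if (!is.null(fw$mask)) dX <- dX * fw$mask
  agg <- rowsum(dX, group = fw$ids)
  grads$emb[as.integer(rownames(agg)), ] <-
    grads$emb[as.integer(rownames(agg)), , drop = FALSE] + agg
  list(nll = nll, grads = grads, n_sentences = length(fw$rows))
}

clip_grads <- function(grads, clip) {
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(clip) && nrm > clip) grads <- lapply(grads, function(g) g * (clip / nrm))
  grads
}

adam_init <- function(params) {
  list(t = 0L, m = zero_grads(params), v = zero_grads(params))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

prepare_doc <- function(doc, vocab, tags) {
  spans <- doc$sentence_spans
  sents <- lapply(seq_len(nrow(spans)), function(j) {
    tokens_to_ids(split_chars(slice_text(doc$text, spans[j, "start"], spans[j, "end"])),
                  vocab)
  })
  gold <- lapply(encode_bio(doc), function(lab) match(lab, tags$labels))
  list(sents = sents, gold = gold)
}

#' Fit a medical NER tagger
#'
#' Trains a character-level BiLSTM-CRF (`variant = "bilstm_crf"`) or its
#' document-attention extension (`variant = "attention_bilstm_crf"`) on a
#' corpus of annotated documents. Training minimizes the negative CRF
#' log-likelihood of the gold tag paths with Adam at batch size one: the
#' baseline takes one optimizer step per sentence, the attention variant one
#' step per document (its attention context spans the document).
#'
#' @param corpus A list of [ner_document()] objects with gold entities.
#' @param variant Model variant.
#' @param embeddings Optional pre-trained vectors from [load_word2vec()];
#'   characters found there are initialized from them.
#' @param control A [medner_control()] object.
#' @param ... Convenience overrides for single `control` fields, e.g.
#'   `epochs = 10`.
#' @return An object of class `medner` with components `params` (weights),
#'   `vocab`, `variant`, `control`, `tags` and `loss_history` (mean
#'   per-sentence negative log-likelihood per epoch).
#' @seealso [predict.medner()], [medner_loss()], [save_medner()]
#' @export
medner <- function(corpus, variant = c("bilstm_crf", "attention_bilstm_crf"),
                   embeddings = NULL, control = medner_control(), ...) {
  variant <- match.arg(variant)
  dots <- list(...)
  if (length(dots)) control <- do.call(medner_control, utils::modifyList(
    unclass(control)[names(formals(medner_control))], dots))
  corpus <- as_corpus(corpus)
  if (!length(corpus)) stop("training corpus is empty", call. = FALSE)
  tags <- medner_tags()
  vocab <- build_vocab(corpus)
  cl <- match.call()
  fit <- with_seed(control$seed, {
    table <- embedding_table(vocab, d = control$dim, pretrained = embeddings,
                             seed = control$seed)
    params <- init_params(table$matrix, ncol(table$matrix), control$hidden,
                          tags$k, variant)
    prep <- lapply(corpus, prepare_doc, vocab = vocab, tags = tags)
    units <- if (variant == "attention_bilstm_crf") {
      Filter(function(u) length(u$sents) > 0, prep)
    } else {
      us <- list()
      for (p in prep) for (s in seq_along(p$sents)) {
        us[[length(us) + 1L]] <- list(sents = p$sents[s], gold = p$gold[s])
      }
      us
    }
    if (!length(units)) stop("corpus contains no non-empty sentences", call. = FALSE)
    state <- adam_init(params)
    history <- numeric(control$epochs)
    for (ep in seq_len(control$epochs)) {
      ord <- sample.int(length(units))
      tot_nll <- 0; tot_sent <- 0L
      for (ui in ord) {
        u <- units[[ui]]
        res <- unit_loss_grad(params, variant, u$sents, u$gold,
                              dropout = control$dropout, training = TRUE,
                              max_doc_tokens = control$max_doc_tokens)
        if (is.null(res)) next
        if (!is.finite(res$nll)) {
          stop("non-finite training loss at epoch ", ep,
               "; try a lower learning rate", call. = FALSE)
        }
        g <- clip_grads(res$grads, control$clip)
        upd <- adam_step(params, g, state, control$learning_rate)
        params <- upd$params; state <- upd$state
        tot_nll <- tot_nll + res$nll; tot_sent <- tot_sent + res$n_sentences
      }
      history[ep] <- tot_nll / max(tot_sent, 1L)
    }
    list(params = params, history = history,
         n_sentences = sum(vapply(prep, function(p) length(p$sents), integer(1))))
  })
  structure(list(params = fit$params, vocab = vocab, variant = variant,
                 control = control, tags = tags,
                 loss_history = fit$history, n_sentences = fit$n_sentences,
                 call = cl),
            class = "medner")
}

#' Predict entities for new documents
#'
#' Runs the encoder (plus attention for the attention variant), decodes each
#' sentence with [crf_viterbi()] and converts the BIO tags into entities with
#' document-level offsets.
#'
#' @param object A fitted [medner()] model.
#' @param newdata A list of [ner_document()] objects (or a single document);
#'   gold entities, if present, are ignored.
#' @param ... Unused.
#' @return A named list (by `doc_id`) of entity data frames.
#' @export
predict.medner <- function(object, newdata, ...) {
  corpus <- as_corpus(newdata)
  A_dec <- object$params$A
  if (object$control$forbid_invalid_transitions) {
    A_dec[bio_transition_mask()] <- -1e4
  }
  out <- lapply(corpus, function(doc) {
    spans <- doc$sentence_spans
    if (nrow(spans) == 0L) return(empty_entities())
    sents <- lapply(seq_len(nrow(spans)), function(j) {
      tokens_to_ids(split_chars(slice_text(doc$text, spans[j, "start"], spans[j, "end"])),
                    object$vocab)
    })
    fw <- unit_forward(object$params, object$variant, sents,
                       training = FALSE,
                       max_doc_tokens = object$control$max_doc_tokens)
    tag_seqs <- lapply(seq_along(fw$rows), function(s) {
      vit <- crf_viterbi(fw$P[fw$rows[[s]], , drop = FALSE], A_dec)
      object$tags$labels[vit$path]
    })
    decode_bio(tag_seqs, doc)
  })
  names(out) <- corpus_ids(corpus)
  out
}

#' Document-level training loss of a fitted model
#'
#' Sum over the document's sentences of the negative CRF log-likelihood of
#' the gold tag path, evaluated without dropout.
#'
#' @param object A fitted [medner()] model.
#' @param document An [ner_document()] with gold entities.
#' @return A single non-negative number.
#' @export
medner_loss <- function(object, document) {
  prep <- prepare_doc(document, object$vocab, object$tags)
  if (!length(prep$sents)) return(0)
  res <- unit_loss_grad(object$params, object$variant, prep$sents, prep$gold,
                        dropout = 0, training = FALSE,
                        max_doc_tokens = object$control$max_doc_tokens)
  if (is.null(res)) 0 else res$nll
}

#' @export
print.medner <- function(x, ...) {
  cat("Medical NER tagger (", x$variant, ")\n", sep = "")
  cat("  vocabulary: ", length(x$vocab), " characters; embedding dim ",
      ncol(x$params$emb), "; hidden ", ncol(x$params$f_Wh), "/direction\n", sep = "")
  cat("  trained ", length(x$loss_history), " epochs on ", x$n_sentences,
      " sentences; final mean sentence NLL ",
      format(utils::tail(x$loss_history, 1), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.medner <- function(object, ...) {
  n_par <- sum(vapply(object$params, length, integer(1)))
  structure(list(model = object, n_parameters = n_par), class = "summary.medner")
}

#' @export
print.summary.medner <- function(x, ...) {
  print(x$model)
  cat("  parameters: ", x$n_parameters, "\n", sep = "")
  h <- x$model$loss_history
  cat("  loss history (mean sentence NLL by epoch):\n")
  print(round(h, 4))
  invisible(x)
}

#' @export
coef.medner <- function(object, ...) {
  ts <- object$tags
  A <- object$params$A
  dimnames(A) <- list(c(ts$labels, "START", "STOP"), c(ts$labels, "START", "STOP"))
  list(transitions = A)
}

#' @export
logLik.medner <- function(object, ...) {
  ll <- -utils::tail(object$loss_history, 1) * object$n_sentences
  structure(ll, df = sum(vapply(object$params, length, integer(1))),
            nobs = object$n_sentences, class = "logLik")
}

#' @export
plot.medner <- function(x, ...) {
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "b",
                 xlab = "epoch", ylab = "mean sentence NLL",
                 main = paste("Training loss:", x$variant), ...)
  invisible(x)
}

MEDNER_CHECKPOINT_VERSION <- 1L

#' Save / load a model checkpoint
#'
#' The checkpoint is a single versioned archive holding the configuration,
#' vocabulary and all weight tensors. Loading an archive with a different
#' format version fails loudly.
#'
#' @param object A fitted [medner()] model.
#' @param path Checkpoint file.
#' @return `save_medner()` returns `path` invisibly; `read_medner()` returns
#'   the model.
#' @export
save_medner <- function(object, path) {
  saveRDS(list(format_version = MEDNER_CHECKPOINT_VERSION,
               model = unclass(object)), path)
  invisible(path)
}

#' @rdname save_medner
#' @export
read_medner <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format_version, MEDNER_CHECKPOINT_VERSION)) {
    stop("checkpoint format version ", obj$format_version %||% "<missing>",
         " does not match supported version ", MEDNER_CHECKPOINT_VERSION,
         call. = FALSE)
  }
  structure(obj$model, class = "medner")
}
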