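# Character vocabulary and embedding table, optional pre-trained vectors in
# word2vec text format, and inverted dropout on the look-up layer.

UNK_TOKEN <- "<unk>"
PAD_TOKEN <- "<pad>"

#' Build a character vocabulary from a corpus
#'
#' Tokens are single characters. Two ids are reserved: `<pad>` (1, unused at
#' batch size one but kept for format stability) and `<unk>` (2), the
#' fallback for characters unseen in training.
#'
#' @param corpus List of [ner_document()] objects.
#' @return Named integer vector mapping token to id.
#' @export
build_vocab <- function(corpus) {
  corpus <- as_corpus(corpus)
  chars <- sort(unique(unlist(lapply(corpus, function(d) split_chars(d$text)))))
  toks <- c(PAD_TOKEN, UNK_TOKEN, chars)
  stats::setNames(seq_along(toks), toks)
}

tokens_to_ids <- function(chars, vocab) {
  ids <- unname(vocab[chars])
  ids[is.na(ids)] <- vocab[[UNK_TOKEN]]
  as.integer(ids)
}

#' Load word vectors in word2vec text format
#'
#' The format is a header line `"<count> <dim>"` followed by one
#' `"token v1 ... v_d"` line per word.
#'
#' @param path Path to the vector file (UTF-8).
#' @return A list with `tokens` (character) and `vectors` (numeric matrix,
#'   one row per token).
#' @export
load_word2vec <- function(path) {
  lines <- read_utf8(path)
  if (!length(lines)) stop("empty word2vec file: ", path, call. = FALSE)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(header) != 2L) stop("malformed word2vec header: '", lines[1], "'", call. = FALSE)
  count <- as.integer(header[1]); d <- as.integer(header[2])
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) != count) {
    stop("word2vec header announces ", count, " vectors but file has ",
         length(body), call. = FALSE)
  }
  toks <- character(count)
  mat <- matrix(0, count, d)
  for (i in seq_len(count)) {
    parts <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(parts) != d + 1L) {
      stop("malformed word2vec line ", i + 1L, ": expected ", d, " values",
           call. = FALSE)
    }
    toks[i] <- parts[1]
    mat[i, ] <- as.numeric(parts[-1])
  }
  stopifnot_finite(mat, "word2vec vectors")
  list(tokens = toks, vectors = mat)
}

#' Create an embedding table
#'
#' Rows for tokens found in `pretrained` are copied from it; all remaining
#' rows (including `<unk>`) are sampled uniformly from (-0.25, 0.25) under
#' the given seed.
#'
#' @param vocab Named integer vector from [build_vocab()].
#' @param d Embedding dimension (ignored, with a message, if `pretrained`
#'   fixes it).
#' @param pretrained Optional result of [load_word2vec()].
#' @param seed Seed for the random rows.
#' @return A list with `vocab` and `matrix` (`|vocab| x d`).
#' @export
embedding_table <- function(vocab, d = 100L, pretrained = NULL, seed = 1L) {
  if (!is.null(pretrained)) d <- ncol(pretrained$vectors)
  mat <- with_seed(seed, matrix(stats::runif(length(vocab) * d, -0.25, 0.25),
                                length(vocab), d))
  if (!is.null(pretrained)) {
    idx <- match(names(vocab), pretrained$tokens)
    hit <- which(!is.na(idx))
    if (length(hit)) mat[hit, ] <- pretrained$vectors[idx[hit], , drop = FALSE]
  }
  mat[vocab[[PAD_TOKEN]], ] <- 0
  list(vocab = vocab, matrix = mat)
}

#' Embed a token-id sequence with inverted dropout
#'
#' During training each embedding coordinate is zeroed independently with
#' probability `dropout` and the survivors are scaled by `1 / (1 - dropout)`,
#' so the expected output equals the embedding row. At prediction time the
#' look-up is exact.
#'
#' @param ids Integer token ids.
#' @param table An [embedding_table()].
#' @param dropout Dropout rate in `[0, 1)`.
#' @param training Logical; dropout is applied only when `TRUE`.
#' @return A list with `X` (the `length(ids) x d` embedded sequence) and
#'   `mask` (the applied dropout scaling, or `NULL` outside training).
#' @export
embed_sequence <- function(ids, table, dropout = 0, training = FALSE) {
  if (length(ids) && (any(ids < 1L) || any(ids > nrow(table$matrix)))) {
    stop("token id out of range for embedding table", call. = FALSE)
  }
  X <- table$matrix[ids, , drop = FALSE]
  mask <- NULL
  if (training && dropout > 0) {
    keep <- matrix(stats::runif(length(X)) >= dropout, nrow(X), ncol(X))
    mask <- keep / (1 - dropout)
    X <- X * mask
  }
  list(X = X, mask = mask)
}
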