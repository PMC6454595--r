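# Document-level attention: pairwise bilinear similarity scores over word
# embeddings, a row-wise softmax attention matrix, and the global context
# vectors that are concatenated to the BiLSTM states.

#' Pairwise attention score
#'
#' The similarity score between two word embeddings is the bilinear form
#' `(x_i - x_j)' W (x_i - x_j)` on their difference vector. With the default
#' initialization `W = -I` this is the negative squared Euclidean distance,
#' so nearer embeddings receive larger attention weight after the softmax.
#'
#' @param x_i,x_j Numeric vectors of equal length `d`.
#' @param W A `d x d` weight matrix.
#' @return A single real score.
#' @export
#' @examples
#' attention_score(c(1, 0), c(0, 1), diag(2))    #  2
#' attention_score(c(1, 0), c(0, 1), -diag(2))   # -2
attention_score <- function(x_i, x_j, W) {
  if (length(x_i) != length(x_j) || nrow(W) != length(x_i) || ncol(W) != length(x_i)) {
    stop("dimension mismatch between embeddings and weight matrix", call. = FALSE)
  }
  d <- x_i - x_j
  drop(crossprod(d, W %*% d))
}

# pairwise score matrix S[i, j] = (x_i - x_j)' W (x_i - x_j), vectorized via
# the expansion x_i'Wx_i + x_j'Wx_j - x_i'Wx_j - x_j'Wx_i
attention_scores_all <- function(X, W) {
  Q <- X %*% W
  q <- rowSums(Q * X)
  M1 <- tcrossprod(Q, X)         # M1[i, j] = x_i' W x_j
  outer(q, rep(1, nrow(X))) + outer(rep(1, nrow(X)), q) - M1 - t(M1)
}

#' Document attention matrix
#'
#' Row-wise softmax of the pairwise scores: entry `(i, j)` is the attention
#' weight of word `j` when tagging word `i`. Every row sums to one.
#'
#' @param X `N x d` matrix of word embeddings for all tokens of a document.
#' @param W `d x d` attention weight matrix.
#' @return An `N x N` attention matrix with rows summing to 1.
#' @export
#' @examples
#' X <- rbind(c(1, 0), c(0, 1))
#' attention_matrix(X, -diag(2))  # row 1 = softmax(0, -2)
attention_matrix <- function(X, W) {
  if (!is.matrix(X) || nrow(X) < 1L) stop("X must be a matrix with N >= 1 rows", call. = FALSE)
  if (nrow(W) != ncol(X) || ncol(W) != ncol(X)) {
    stop("W must be d x d with d = ncol(X)", call. = FALSE)
  }
  S <- attention_scores_all(X, W)
  row_softmax(S)
}

row_softmax <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

#' Global context vectors
#'
#' `G = A H` weights every token's encoder state by the document attention,
#' and `Z = [G; H]` concatenates the global vector with the token's own
#' state; `Z` feeds the tanh emission layer of the attention variant.
#'
#' @param A_att `N x N` attention matrix.
#' @param H `N x m` encoder output (concatenated BiLSTM states).
#' @return A list with `G` (`N x m`) and `Z` (`N x 2m`).
#' @export
global_context <- function(A_att, H) {
  if (nrow(A_att) != ncol(A_att)) stop("attention matrix must be square", call. = FALSE)
  if (nrow(H) != nrow(A_att)) {
    stop("H must have as many rows as the attention matrix", call. = FALSE)
  }
  G <- A_att %*% H
  list(G = G, Z = cbind(G, H))
}
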