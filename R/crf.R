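# Linear-chain CRF mathematics over START/STOP-augmented transitions.
#
# Conventions: the emission matrix P is n x k (position x tag, any finite real
# scores); the transition matrix A is (k + 2) x (k + 2) with row/column k + 1
# the START state and k + 2 the STOP state. Tag paths are 1-based integer
# vectors with entries in 1..k. All computations are in log space.

check_crf_dims <- function(P, A, y = NULL) {
  if (!is.matrix(P) || !is.matrix(A)) stop("P and A must be matrices", call. = FALSE)
  k <- ncol(P)
  if (nrow(A) != k + 2L || ncol(A) != k + 2L) {
    stop("transition matrix must be (k + 2) x (k + 2) with k = ", k,
         "; got ", nrow(A), " x ", ncol(A), call. = FALSE)
  }
  stopifnot_finite(P, "emission matrix")
  stopifnot_finite(A, "transition matrix")
  if (!is.null(y)) {
    if (length(y) != nrow(P)) {
      stop("tag path length (", length(y), ") does not match sentence length (",
           nrow(P), ")", call. = FALSE)
    }
    if (length(y) && (any(y < 1L) || any(y > k))) {
      stop("tag path entries must lie in 1..k", call. = FALSE)
    }
  }
  k
}

#' Score of one tag path under a linear-chain CRF
#'
#' Computes the unnormalized path score: the START transition into the first
#' tag, the per-position emission scores, the tag-to-tag transitions, and the
#' transition from the last tag into STOP.
#'
#' @param P Emission matrix, `n x k`.
#' @param A Transition matrix, `(k + 2) x (k + 2)`; index `k + 1` is START,
#'   `k + 2` is STOP.
#' @param y Integer tag path of length `n`, entries in `1..k`.
#' @return The path score (a single real).
#' @export
#' @examples
#' P <- matrix(c(1, 2, 3, 4), 2, byrow = TRUE)
#' A <- matrix(0.5, 4, 4)
#' crf_path_score(P, A, c(2, 1))  # 6.5
crf_path_score <- function(P, A, y) {
  k <- check_crf_dims(P, A, y)
  n <- nrow(P)
  if (n == 0L) return(A[k + 1L, k + 2L])
  s <- A[k + 1L, y[1]] + sum(P[cbind(seq_len(n), y)]) + A[y[n], k + 2L]
  if (n > 1L) s <- s + sum(A[cbind(y[-n], y[-1])])
  s
}

#' Log partition function of a linear-chain CRF
#'
#' Log of the sum of exponentiated path scores over all `k^n` tag paths,
#' computed by the forward algorithm with log-sum-exp recursions (stable for
#' scores up to about 1e4 in magnitude).
#'
#' @inheritParams crf_path_score
#' @return `log sum_y exp(crf_path_score(P, A, y))`.
#' @export
crf_log_partition <- function(P, A) {
  k <- check_crf_dims(P, A)
  n <- nrow(P)
  if (n == 0L) return(A[k + 1L, k + 2L])
  Ak <- A[seq_len(k), seq_len(k), drop = FALSE]
  a <- A[k + 1L, seq_len(k)] + P[1, ]
  if (n > 1L) {
    for (t in 2:n) {
      M <- a + Ak                      # M[i, j] = a_i + A[i, j]
      tM <- t(M)
      m <- tM[cbind(seq_len(k), max.col(tM, ties.method = "first"))]
      a <- m + log(colSums(exp(sweep(M, 2L, m)))) + P[t, ]
    }
  }
  logsumexp(a + A[seq_len(k), k + 2L])
}

#' CRF log-likelihood of a tag path
#'
#' `crf_path_score(P, A, y) - crf_log_partition(P, A)`; always non-positive.
#'
#' @inheritParams crf_path_score
#' @return The log-probability of `y`.
#' @export
crf_log_likelihood <- function(P, A, y) {
  crf_path_score(P, A, y) - crf_log_partition(P, A)
}

#' Viterbi decoding
#'
#' Returns a maximum-score tag path and its score. Ties are broken
#' deterministically in favour of the lowest tag index at the earliest
#' position at which optimal paths differ (the decode is the
#' lexicographically smallest argmax path).
#'
#' @inheritParams crf_path_score
#' @return A list with elements `path` (integer vector of length `n`) and
#'   `score` (equal to `crf_path_score(P, A, path)`).
#' @export
crf_viterbi <- function(P, A) {
  k <- check_crf_dims(P, A)
  n <- nrow(P)
  if (n == 0L) return(list(path = integer(0), score = A[k + 1L, k + 2L]))
  Ak <- A[seq_len(k), seq_len(k), drop = FALSE]
  # beta[t, j]: best score of a path suffix starting at position t with tag j
  # (including P[t, j] and the final STOP transition)
  beta <- matrix(0, n, k)
  beta[n, ] <- P[n, ] + A[seq_len(k), k + 2L]
  if (n > 1L) {
    for (t in (n - 1L):1L) {
      M <- sweep(Ak, 2L, beta[t + 1L, ], "+")   # M[j, j'] = A[j, j'] + beta[t+1, j']
      beta[t, ] <- P[t, ] + apply(M, 1L, max)
    }
  }
  path <- integer(n)
  first_scores <- A[k + 1L, seq_len(k)] + beta[1, ]
  path[1] <- which.max(first_scores)
  score <- first_scores[path[1]]
  if (n > 1L) {
    for (t in 2:n) {
      path[t] <- which.max(Ak[path[t - 1L], ] + beta[t, ])
    }
  }
  list(path = path, score = score)
}

# Forward-backward pass returning the gradient of the negative log-likelihood
# -log p(y | X) with respect to P and A (expected minus observed feature
# counts). Used by the tagger's training loop; also returns the NLL itself.
crf_nll_grad <- function(P, A, y) {
  k <- check_crf_dims(P, A, y)
  n <- nrow(P)
  ks <- seq_len(k)
  Ak <- A[ks, ks, drop = FALSE]
  if (n == 0L) {
    return(list(nll = 0, dP = P * 0, dA = A * 0))
  }
  # log-alpha / log-beta tables
  la <- matrix(-Inf, n, k); lb <- matrix(-Inf, n, k)
  la[1, ] <- A[k + 1L, ks] + P[1, ]
  if (n > 1L) {
    for (t in 2:n) {
      M <- la[t - 1L, ] + Ak
      tM <- t(M)
      m <- tM[cbind(ks, max.col(tM, ties.method = "first"))]
      la[t, ] <- m + log(colSums(exp(sweep(M, 2L, m)))) + P[t, ]
    }
  }
  lb[n, ] <- A[ks, k + 2L]
  if (n > 1L) {
    for (t in (n - 1L):1L) {
      M <- sweep(Ak, 2L, lb[t + 1L, ] + P[t + 1L, ], "+")
      m <- M[cbind(ks, max.col(M, ties.method = "first"))]
      lb[t, ] <- m + log(rowSums(exp(M - m)))
    }
  }
  logZ <- logsumexp(la[n, ] + lb[n, ])
  # position marginals
  gamma <- exp(la + lb - logZ)
  dP <- gamma
  dP[cbind(seq_len(n), y)] <- dP[cbind(seq_len(n), y)] - 1
  dA <- A * 0
  dA[k + 1L, ks] <- gamma[1, ]
  dA[k + 1L, y[1]] <- dA[k + 1L, y[1]] - 1
  dA[ks, k + 2L] <- gamma[n, ]
  dA[y[n], k + 2L] <- dA[y[n], k + 2L] - 1
  if (n > 1L) {
    for (t in seq_len(n - 1L)) {
      xi <- exp(outer(la[t, ], lb[t + 1L, ] + P[t + 1L, ], "+") + Ak - logZ)
      dA[ks, ks] <- dA[ks, ks] + xi
      dA[y[t], y[t + 1L]] <- dA[y[t], y[t + 1L]] - 1
    }
  }
  nll <- logZ - crf_path_score(P, A, y)
  list(nll = nll, dP = dP, dA = dA)
}

# mask of transitions that violate the BIO schema (O -> I-X, B-X/I-X -> I-Y,
# START -> I-X); used only when constrained decoding is requested
bio_transition_mask <- function() {
  ts <- medner_tags()
  k <- ts$k
  lab <- ts$labels
  bad <- matrix(FALSE, k + 2L, k + 2L)
  cat_of <- tag_category(lab)
  is_i <- startsWith(lab, "I-")
  for (j in which(is_i)) {
    ok_prev <- which(!is.na(cat_of) & cat_of == cat_of[j])
    bad[seq_len(k), j] <- TRUE
    bad[ok_prev, j] <- FALSE
    bad[ts$start, j] <- TRUE
  }
  bad
}
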