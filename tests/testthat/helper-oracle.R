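# Independent brute-force oracles: enumerate all k^n tag paths explicitly.
# These never call the dynamic-programming implementations they check.

enumerate_paths <- function(n, k) {
  if (n == 0L) return(matrix(integer(0), nrow = 1, ncol = 0))
  as.matrix(expand.grid(rep(list(seq_len(k)), n)))
}

# path score computed by direct term-by-term bookkeeping
oracle_path_score <- function(P, A, y) {
  k <- ncol(P)
  n <- nrow(P)
  if (n == 0L) return(A[k + 1L, k + 2L])
  s <- A[k + 1L, y[1]]
  for (t in seq_len(n)) {
    s <- s + P[t, y[t]]
    if (t > 1L) s <- s + A[y[t - 1L], y[t]]
  }
  s + A[y[n], k + 2L]
}

oracle_all_scores <- function(P, A) {
  paths <- enumerate_paths(nrow(P), ncol(P))
  apply(paths, 1L, function(y) oracle_path_score(P, A, as.integer(y)))
}

oracle_log_partition <- function(P, A) {
  s <- oracle_all_scores(P, A)
  m <- max(s)
  m + log(sum(exp(s - m)))
}

oracle_viterbi_max <- function(P, A) max(oracle_all_scores(P, A))

random_crf_instance <- function(n = NULL, k = NULL, scale = 2) {
  if (is.null(n)) n <- sample(1:6, 1)
  if (is.null(k)) k <- sample(1:5, 1)
  list(P = matrix(stats::rnorm(n * k, sd = scale), n, k),
       A = matrix(stats::rnorm((k + 2)^2, sd = scale), k + 2, k + 2))
}
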