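# Small internal helpers. Character offsets are 0-based, half-open [start, end)
# and count Unicode code points, matching the tagged-item annotation format.

# slice text at [start, end), 0-based code points
slice_text <- function(text, start, end) {
  if (!length(start)) return(character(0))
  substring(text, start + 1L, end)
}

n_chars <- function(text) nchar(text, type = "chars")

split_chars <- function(text) {
  if (!nzchar(text)) return(character(0))
  strsplit(text, "", fixed = FALSE)[[1]]
}

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic per-document seed, kept below 2^31
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483629
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}
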