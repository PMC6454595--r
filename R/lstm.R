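# Long short-term memory cell: forward pass and backpropagation through time.
# Gate order in the stacked pre-activation is (input, forget, output, cell).
# These are internal building blocks of the tagger; their gradients are
# pinned by finite-difference checks in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

# X: T x d input sequence; Wx: 4h x d; Wh: 4h x h; b: 4h.
# Returns hidden states H (T x h) plus the caches BPTT needs.
lstm_forward <- function(X, Wx, Wh, b) {
  Tn <- nrow(X)
  hsz <- ncol(Wh)
  i1 <- seq_len(hsz); i2 <- hsz + i1; i3 <- 2L * hsz + i1; i4 <- 3L * hsz + i1
  Ain <- X %*% t(Wx)
  H <- matrix(0, Tn, hsz); C <- matrix(0, Tn, hsz)
  Gi <- matrix(0, Tn, hsz); Gf <- matrix(0, Tn, hsz)
  Go <- matrix(0, Tn, hsz); Gg <- matrix(0, Tn, hsz); Tc <- matrix(0, Tn, hsz)
  h <- numeric(hsz); cc <- numeric(hsz)
  for (t in seq_len(Tn)) {
    a <- Ain[t, ] + drop(Wh %*% h) + b
    gi <- sigmoid(a[i1]); gf <- sigmoid(a[i2]); go <- sigmoid(a[i3]); gg <- tanh(a[i4])
    cc <- gf * cc + gi * gg
    tc <- tanh(cc)
    h <- go * tc
    Gi[t, ] <- gi; Gf[t, ] <- gf; Go[t, ] <- go; Gg[t, ] <- gg
    C[t, ] <- cc; Tc[t, ] <- tc; H[t, ] <- h
  }
  list(H = H, C = C, Gi = Gi, Gf = Gf, Go = Go, Gg = Gg, Tc = Tc)
}

# dH: T x h gradient w.r.t. the hidden states. Returns parameter gradients
# and the gradient w.r.t. the inputs X.
lstm_backward <- function(cache, X, Wx, Wh, dH) {
  Tn <- nrow(X)
  hsz <- ncol(Wh)
  dA <- matrix(0, Tn, 4L * hsz)
  dh_next <- numeric(hsz); dc_next <- numeric(hsz)
  i1 <- seq_len(hsz); i2 <- hsz + i1; i3 <- 2L * hsz + i1; i4 <- 3L * hsz + i1
  for (t in rev(seq_len(Tn))) {
    cprev <- if (t > 1L) cache$C[t - 1L, ] else numeric(hsz)
    dh <- dH[t, ] + dh_next
    go <- cache$Go[t, ]; tc <- cache$Tc[t, ]
    gi <- cache$Gi[t, ]; gf <- cache$Gf[t, ]; gg <- cache$Gg[t, ]
    do_ <- dh * tc * go * (1 - go)
    dc <- dc_next + dh * go * (1 - tc^2)
    di <- dc * gg * gi * (1 - gi)
    df <- dc * cprev * gf * (1 - gf)
    dg <- dc * gi * (1 - gg^2)
    da <- c(di, df, do_, dg)
    dA[t, ] <- da
    dh_next <- drop(crossprod(Wh, da))
    dc_next <- dc * gf
  }
  dWh <- if (Tn > 1L) {
    crossprod(dA[-1L, , drop = FALSE], cache$H[-Tn, , drop = FALSE])
  } else matrix(0, 4L * hsz, hsz)
  list(dWx = crossprod(dA, X), dWh = dWh, db = colSums(dA), dX = dA %*% Wx)
}

# Bidirectional encoding of one sentence: forward LSTM over X and a second
# LSTM over the reversed sequence, hidden states concatenated per position.
bilstm_sentence <- function(X, fwd, bwd) {
  Tn <- nrow(X)
  rev_idx <- rev(seq_len(Tn))
  cf <- lstm_forward(X, fwd$Wx, fwd$Wh, fwd$b)
  cb <- lstm_forward(X[rev_idx, , drop = FALSE], bwd$Wx, bwd$Wh, bwd$b)
  list(H = cbind(cf$H, cb$H[rev_idx, , drop = FALSE]), cf = cf, cb = cb)
}

bilstm_sentence_backward <- function(enc, X, fwd, bwd, dH) {
  hsz <- ncol(fwd$Wh)
  Tn <- nrow(X)
  rev_idx <- rev(seq_len(Tn))
  gf <- lstm_backward(enc$cf, X, fwd$Wx, fwd$Wh, dH[, seq_len(hsz), drop = FALSE])
  gb <- lstm_backward(enc$cb, X[rev_idx, , drop = FALSE], bwd$Wx, bwd$Wh,
                      dH[rev_idx, hsz + seq_len(hsz), drop = FALSE])
  list(fwd = gf, bwd = gb, dX = gf$dX + gb$dX[rev_idx, , drop = FALSE])
}
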