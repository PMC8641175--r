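# Low-level neural-network layers used by the window classifier.
#
# Activations flow through the convolutional encoder as a matrix `x` of
# shape (h*w*N) x C together with its spatial dims: row index
# i + (j-1)*h + (n-1)*h*w addresses spatial position (i, j) of window n.
# The allocation-heavy kernels (3x3 same-padding convolution via im2col,
# SE channel re-weighting, max pooling, per-window channel sums) live in
# src/layers.cpp so their multi-megabyte temporaries stay off R's heap;
# the small dense/recurrent algebra stays in R. Backward passes are
# hand-derived and verified against central finite differences in the
# test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

add_bias <- function(Y, b) sweep(Y, 2L, b, "+")

# ---- convolution ----------------------------------------------------------

# Weights are stored as a (9*cin) x cout matrix; row block o holds the
# kernel tap for spatial offset o (column-major over a 3x3 neighbourhood).
conv_fwd <- function(x, h, w, N, W, b) {
  list(y = conv3_fwd_cpp(x, h, w, N, W, b), x = x, h = h, w = w, N = N)
}

conv_bwd <- function(dY, cache, W) {
  conv3_bwd_cpp(cache$x, dY, cache$h, cache$w, cache$N, W)
}

# ---- squeeze-and-excitation ----------------------------------------------

se_fwd <- function(x, h, w, N, W1, b1, W2, b2) {
  hw <- h * w
  s <- group_sums_cpp(x, hw) / hw            # N x C channel means
  a1 <- pmax(add_bias(s %*% W1, b1), 0)
  gate <- sigmoid(add_bias(a1 %*% W2, b2))
  list(y = group_scale_cpp(x, gate, hw), s = s, a1 = a1, gate = gate)
}

se_bwd <- function(dY, cache, x, h, w, W1, W2) {
  hw <- h * w
  dgate <- group_sums_prod_cpp(dY, x, hw)
  dz2 <- dgate * cache$gate * (1 - cache$gate)
  dW2 <- crossprod(cache$a1, dz2)
  da1 <- dz2 %*% t(W2)
  dz1 <- da1 * (cache$a1 > 0)
  dW1 <- crossprod(cache$s, dz1)
  ds <- dz1 %*% t(W1)
  dx <- group_scale_affine_cpp(dY, cache$gate, ds / hw, hw)
  list(dx = dx, dW1 = dW1, db1 = colSums(dz1), dW2 = dW2, db2 = colSums(dz2))
}

# ---- max pooling ----------------------------------------------------------

maxpool_fwd <- function(x, h, w, N, ph, pw) {
  r <- maxpool_fwd_cpp(x, h, w, N, ph, pw)
  list(y = r$y, which_k = r$which_k, h = h, w = w, N = N, ph = ph, pw = pw)
}

maxpool_bwd <- function(dY, cache, cin) {
  maxpool_bwd_cpp(dY, cache$which_k, cache$h, cache$w, cache$N, cache$ph,
                  cache$pw)
}

# ---- global average pool --------------------------------------------------

gap_fwd <- function(x, h, w, N) {
  list(y = group_sums_cpp(x, h * w) / (h * w), hw = h * w)
}

gap_bwd <- function(dY, cache, h, w) group_expand_cpp(dY / cache$hw, cache$hw)

# ---- dense / dropout ------------------------------------------------------

dense_fwd <- function(x, W, b) add_bias(x %*% W, b)

dense_bwd <- function(dY, x, W) {
  list(dx = dY %*% t(W), dW = crossprod(x, dY), db = colSums(dY))
}

dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, mask = NULL))
  mask <- matrix((stats::runif(length(x)) >= rate) / (1 - rate),
                 nrow(x), ncol(x))
  list(y = x * mask, mask = mask)
}

# ---- LSTM -----------------------------------------------------------------

# One direction of an LSTM over a t-major batch. `X` is a list of T
# matrices [B x D]. Gate order in the fused weight matrices: input, forget,
# output, candidate. Returns hidden states at the original time positions.
lstm_fwd <- function(X, Wx, Wh, b, reverse = FALSE) {
  T_len <- length(X)
  B <- nrow(X[[1L]])
  H <- ncol(Wh) %/% 4L
  ts <- if (reverse) rev(seq_len(T_len)) else seq_len(T_len)
  h_prev <- matrix(0, B, H)
  c_prev <- matrix(0, B, H)
  outs <- vector("list", T_len)
  cache <- vector("list", T_len)
  ii <- seq_len(H); ff <- H + ii; oo <- 2L * H + ii; gg <- 3L * H + ii
  for (t in ts) {
    z <- add_bias(X[[t]] %*% Wx + h_prev %*% Wh, b)
    gi <- sigmoid(z[, ii, drop = FALSE])
    gf <- sigmoid(z[, ff, drop = FALSE])
    go <- sigmoid(z[, oo, drop = FALSE])
    gc <- tanh(z[, gg, drop = FALSE])
    c_t <- gf * c_prev + gi * gc
    tc <- tanh(c_t)
    h_t <- go * tc
    cache[[t]] <- list(gi = gi, gf = gf, go = go, gc = gc, c_prev = c_prev,
                       tc = tc, h_prev = h_prev)
    outs[[t]] <- h_t
    h_prev <- h_t
    c_prev <- c_t
  }
  list(h = outs, cache = cache, reverse = reverse)
}

lstm_bwd <- function(dH, fwd, X, Wx, Wh) {
  T_len <- length(X)
  B <- nrow(X[[1L]])
  H <- ncol(Wh) %/% 4L
  ts <- if (fwd$reverse) rev(seq_len(T_len)) else seq_len(T_len)
  tWx <- t(Wx)
  tWh <- t(Wh)
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(4L * H)
  dX <- vector("list", T_len)
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  for (t in rev(ts)) {
    cc <- fwd$cache[[t]]
    dh <- dH[[t]] + dh_next
    dgo <- dh * cc$tc
    dc <- dc_next + dh * cc$go * (1 - cc$tc^2)
    dgi <- dc * cc$gc
    dgc <- dc * cc$gi
    dgf <- dc * cc$c_prev
    dc_next <- dc * cc$gf
    dZ <- cbind(dgi * cc$gi * (1 - cc$gi),
                dgf * cc$gf * (1 - cc$gf),
                dgo * cc$go * (1 - cc$go),
                dgc * (1 - cc$gc^2))
    dWx <- dWx + crossprod(X[[t]], dZ)
    dWh <- dWh + crossprod(cc$h_prev, dZ)
    db <- db + colSums(dZ)
    dX[[t]] <- dZ %*% tWx
    dh_next <- dZ %*% tWh
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}
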