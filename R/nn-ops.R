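# Minimal neural-network primitives on (batch, time, channel) arrays.
# All layers provide an explicit backward pass; correctness is pinned by
# finite-difference gradient checks in the test suite. Zero padding is used
# everywhere so that outputs at valid positions are independent of how far
# a batch is padded (padding invariance).

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

# --- 1-D convolution, stride 1, "same" zero padding ------------------------

nn_conv1d_forward <- function(x, W, b) {
  d <- dim(x); B <- d[1]; L <- d[2]; Cin <- d[3]
  K <- dim(W)[1]; Cout <- dim(W)[3]
  stopifnot(dim(W)[2] == Cin)
  pl <- (K - 1L) %/% 2L
  xp <- array(0, c(B, L + K - 1L, Cin))
  xp[, pl + seq_len(L), ] <- x
  y <- matrix(rep(b, each = B * L), B * L, Cout)
  for (k in seq_len(K)) {
    Xk <- matrix(xp[, k:(k + L - 1L), , drop = FALSE], B * L, Cin)
    y <- y + Xk %*% matrix(W[k, , ], Cin, Cout)
  }
  list(out = array(y, c(B, L, Cout)), xp = xp)
}

nn_conv1d_backward <- function(dout, cache, W) {
  d <- dim(dout); B <- d[1]; L <- d[2]; Cout <- d[3]
  K <- dim(W)[1]; Cin <- dim(W)[2]
  pl <- (K - 1L) %/% 2L
  dy <- matrix(dout, B * L, Cout)
  dW <- array(0, dim(W))
  dxp <- array(0, dim(cache$xp))
  for (k in seq_len(K)) {
    Xk <- matrix(cache$xp[, k:(k + L - 1L), , drop = FALSE], B * L, Cin)
    dW[k, , ] <- crossprod(Xk, dy)
    dxk <- dy %*% t(matrix(W[k, , ], Cin, Cout))
    dxp[, k:(k + L - 1L), ] <- dxp[, k:(k + L - 1L), ] +
      array(dxk, c(B, L, Cin))
  }
  list(dx = dxp[, pl + seq_len(L), , drop = FALSE],
       dW = dW, db = colSums(dy))
}

# --- ReLU -------------------------------------------------------------------

nn_relu_forward <- function(x) list(out = pmax(x, 0), mask = x > 0)
nn_relu_backward <- function(dout, cache) dout * cache$mask

# --- max pooling, window 2, stride 2, ceil mode -----------------------------

nn_maxpool2_forward <- function(x) {
  d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]
  Lo <- ceiling(L / 2)
  i1 <- seq(1L, L, by = 2L)
  i2 <- i1 + 1L
  a <- x[, i1, , drop = FALSE]
  bb <- array(-Inf, c(B, Lo, C))
  ok <- i2 <= L
  if (any(ok)) bb[, ok, ] <- x[, i2[ok], , drop = FALSE]
  first <- a >= bb
  list(out = pmax(a, bb), first = first, L = L)
}

nn_maxpool2_backward <- function(dout, cache) {
  d <- dim(dout); B <- d[1]; Lo <- d[2]; C <- d[3]
  L <- cache$L
  dx <- array(0, c(B, L, C))
  i1 <- seq(1L, L, by = 2L)
  i2 <- i1 + 1L
  dx[, i1, ] <- dout * cache$first
  ok <- i2 <= L
  if (any(ok)) {
    dx[, i2[ok], ] <- (dout * !cache$first)[, ok, , drop = FALSE]
  }
  dx
}

# --- single-direction LSTM --------------------------------------------------
# Wx: Cin x 4H, Wh: H x 4H, b: 4H. Gate order i, f, g, o. Padded timesteps
# (beyond each sequence's length) are computed but never consumed; their
# output gradients are zero, so no gradient leaks into valid positions.

nn_lstm_forward <- function(x, Wx, Wh, b) {
  d <- dim(x); B <- d[1]; L <- d[2]
  H <- as.integer(ncol(Wx) / 4L)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  out <- array(0, c(B, L, H))
  cache <- vector("list", L)
  ii <- seq_len(H); ff <- H + ii; gg <- 2L * H + ii; oo <- 3L * H + ii
  bmat <- matrix(rep(b, each = B), B, 4L * H)
  for (t in seq_len(L)) {
    xt <- matrix(x[, t, ], B, dim(x)[3])
    G <- xt %*% Wx + h %*% Wh + bmat
    i_g <- nn_sigmoid(G[, ii, drop = FALSE])
    f_g <- nn_sigmoid(G[, ff, drop = FALSE])
    g_g <- tanh(G[, gg, drop = FALSE])
    o_g <- nn_sigmoid(G[, oo, drop = FALSE])
    c_prev <- cc
    cc <- f_g * c_prev + i_g * g_g
    tc <- tanh(cc)
    h_prev <- h
    h <- o_g * tc
    out[, t, ] <- h
    cache[[t]] <- list(xt = xt, i = i_g, f = f_g, g = g_g, o = o_g,
                       c = cc, tc = tc, c_prev = c_prev, h_prev = h_prev)
  }
  list(out = out, cache = cache)
}

nn_lstm_backward <- function(dout, cache, x, Wx, Wh) {
  d <- dim(x); B <- d[1]; L <- d[2]; Cin <- d[3]
  H <- as.integer(ncol(Wx) / 4L)
  ii <- seq_len(H); ff <- H + ii; gg <- 2L * H + ii; oo <- 3L * H + ii
  dWx <- array(0, dim(Wx)); dWh <- array(0, dim(Wh)); db <- numeric(4L * H)
  dx <- array(0, c(B, L, Cin))
  dh <- matrix(0, B, H); dc <- matrix(0, B, H)
  for (t in rev(seq_len(L))) {
    cs <- cache$cache[[t]]
    dh_t <- dh + matrix(dout[, t, ], B, H)
    do_g <- dh_t * cs$tc
    dc <- dc + dh_t * cs$o * (1 - cs$tc^2)
    di <- dc * cs$g
    dg <- dc * cs$i
    df <- dc * cs$c_prev
    dc <- dc * cs$f
    dG <- matrix(0, B, 4L * H)
    dG[, ii] <- di * cs$i * (1 - cs$i)
    dG[, ff] <- df * cs$f * (1 - cs$f)
    dG[, gg] <- dg * (1 - cs$g^2)
    dG[, oo] <- do_g * cs$o * (1 - cs$o)
    dWx <- dWx + crossprod(cs$xt, dG)
    dWh <- dWh + crossprod(cs$h_prev, dG)
    db <- db + colSums(dG)
    dx[, t, ] <- dG %*% t(Wx)
    dh <- dG %*% t(Wh)
  }
  list(dx = dx, dWx = dWx, dWh = dWh, db = db)
}

# Reverse each sequence within its valid length (padding stays in place).
nn_reverse_sequences <- function(x, lengths) {
  y <- array(0, dim(x))
  for (bi in seq_along(lengths)) {
    l <- lengths[bi]
    if (l > 0) y[bi, seq_len(l), ] <- x[bi, rev(seq_len(l)), ]
  }
  y
}

# --- bidirectional LSTM -----------------------------------------------------

nn_bilstm_forward <- function(x, params, lengths) {
  fwd <- nn_lstm_forward(x, params$fwd$Wx, params$fwd$Wh, params$fwd$b)
  xr <- nn_reverse_sequences(x, lengths)
  bwd <- nn_lstm_forward(xr, params$bwd$Wx, params$bwd$Wh, params$bwd$b)
  out_b <- nn_reverse_sequences(bwd$out, lengths)
  d <- dim(fwd$out); H <- d[3]
  out <- array(0, c(d[1], d[2], 2L * H))
  out[, , seq_len(H)] <- fwd$out
  out[, , H + seq_len(H)] <- out_b
  list(out = out, fwd = fwd, bwd = bwd, xr = xr, lengths = lengths)
}

nn_bilstm_backward <- function(dout, cache, x, params) {
  H <- as.integer(dim(dout)[3] / 2L)
  d_f <- dout[, , seq_len(H), drop = FALSE]
  d_b <- dout[, , H + seq_len(H), drop = FALSE]
  gb_f <- nn_lstm_backward(d_f, cache$fwd, x, params$fwd$Wx, params$fwd$Wh)
  d_br <- nn_reverse_sequences(d_b, cache$lengths)
  gb_b <- nn_lstm_backward(d_br, cache$bwd, cache$xr,
                           params$bwd$Wx, params$bwd$Wh)
  dx_b <- nn_reverse_sequences(gb_b$dx, cache$lengths)
  list(dx = gb_f$dx + dx_b,
       fwd = list(dWx = gb_f$dWx, dWh = gb_f$dWh, db = gb_f$db),
       bwd = list(dWx = gb_b$dWx, dWh = gb_b$dWh, db = gb_b$db))
}

# --- Adam optimiser over an arbitrary nested list of numeric arrays ---------

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  tt <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^tt)
    vhat <- v / (1 - beta2^tt)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = tt))
}
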