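# Native sequence-network engine: LSTM, GRU and single-head Transformer
# encoders with analytic backpropagation and an Adam optimizer, written on
# base-R matrix ops (BLAS-backed). Internal; the user-facing surface is in
# forecast.R. Gradients are verified against finite-difference oracles in
# the test suite.
#
# Sequence activations are stored as B x T x F arrays; `matrix(X, B*T, F)`
# flattens them (column-major, batch index fastest) for shared linear maps.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# ---- parameter initialization ------------------------------------------

.init_lstm_layer <- function(n_in, units) {
  b <- numeric(4 * units)
  b[(units + 1):(2 * units)] <- 1  # forget-gate bias
  list(W = .glorot(n_in, 4 * units), U = .glorot(units, 4 * units), b = b)
}

.init_gru_layer <- function(n_in, units) {
  list(W = .glorot(n_in, 3 * units), U = .glorot(units, 3 * units),
       b = numeric(3 * units))
}

.init_dense <- function(n_in, n_out) {
  list(W = .glorot(n_in, n_out), b = numeric(n_out))
}

.init_layernorm <- function(d) list(g = rep(1, d), b = numeric(d))

.init_encoder_layer <- function(d, dff) {
  list(Wq = .glorot(d, d), Wk = .glorot(d, d), Wv = .glorot(d, d),
       Wo = .glorot(d, d), ln1 = .init_layernorm(d),
       ff1 = .init_dense(d, dff), ff2 = .init_dense(dff, d),
       ln2 = .init_layernorm(d))
}

# RNG must already be seeded by the caller
.nn_init <- function(arch, input_dim, output_dim, cfg) {
  if (arch %in% c("lstm", "gru")) {
    u <- cfg$units
    init_layer <- if (arch == "lstm") .init_lstm_layer else .init_gru_layer
    list(arch = arch, cfg = cfg,
         params = list(l1 = init_layer(input_dim, u),
                       l2 = init_layer(u, u),
                       dense = .init_dense(u, cfg$dense_units),
                       out = .init_dense(cfg$dense_units, output_dim)))
  } else if (arch == "transformer") {
    d <- cfg$d_model
    list(arch = arch, cfg = cfg,
         params = list(embed = .init_dense(input_dim, d),
                       enc1 = .init_encoder_layer(d, cfg$ff_dim),
                       enc2 = .init_encoder_layer(d, cfg$ff_dim),
                       dense = .init_dense(d, cfg$dense_units),
                       out = .init_dense(cfg$dense_units, output_dim)))
  } else {
    stop("unknown architecture: ", arch, call. = FALSE)
  }
}

# ---- recurrent layers ---------------------------------------------------

# X: B x T x F. Returns h sequence (B x T x U) and caches for backprop.
.lstm_forward <- function(p, X) {
  dims <- dim(X); B <- dims[1]; T_ <- dims[2]
  u <- ncol(p$U)/4
  i_ix <- 1:u; f_ix <- u + i_ix; g_ix <- 2*u + i_ix; o_ix <- 3*u + i_ix
  h <- matrix(0, B, u); cc <- matrix(0, B, u)
  H <- array(0, c(B, T_, u))
  cache <- vector("list", T_)
  bmat <- matrix(p$b, B, 4*u, byrow = TRUE)
  for (t in seq_len(T_)) {
    xt <- matrix(X[, t, ], B)
    z <- xt %*% p$W + h %*% p$U + bmat
    ig <- .sigmoid(z[, i_ix, drop = FALSE])
    fg <- .sigmoid(z[, f_ix, drop = FALSE])
    gg <- tanh(z[, g_ix, drop = FALSE])
    og <- .sigmoid(z[, o_ix, drop = FALSE])
    c_prev <- cc
    cc <- fg * c_prev + ig * gg
    tc <- tanh(cc)
    h_prev <- h
    h <- og * tc
    H[, t, ] <- h
    cache[[t]] <- list(xt = xt, i = ig, f = fg, g = gg, o = og,
                       c_prev = c_prev, tc = tc, h_prev = h_prev)
  }
  list(H = H, cache = cache, u = u)
}

# dH: B x T x U (zeros except last step when only the last state is used)
.lstm_backward <- function(p, fwd, dH, need_dx = FALSE) {
  cache <- fwd$cache; u <- fwd$u
  T_ <- length(cache); B <- nrow(cache[[1]]$xt)
  dW <- 0 * p$W; dU <- 0 * p$U; db <- 0 * p$b
  dh <- matrix(0, B, u); dc <- matrix(0, B, u)
  dX <- if (need_dx) array(0, c(B, T_, nrow(p$W)))
  tW <- t(p$W); tU <- t(p$U)
  for (t in rev(seq_len(T_))) {
    cc <- cache[[t]]
    dh <- dh + matrix(dH[, t, ], B)
    do_ <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dW <- dW + crossprod(cc$xt, dz)
    dU <- dU + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dh <- dz %*% tU
    dc <- dc * cc$f
    if (need_dx) dX[, t, ] <- dz %*% tW
  }
  list(grads = list(W = dW, U = dU, b = db), dX = dX)
}

.gru_forward <- function(p, X) {
  dims <- dim(X); B <- dims[1]; T_ <- dims[2]
  u <- ncol(p$U)/3
  z_ix <- 1:u; r_ix <- u + z_ix; h_ix <- 2*u + z_ix
  h <- matrix(0, B, u)
  H <- array(0, c(B, T_, u))
  cache <- vector("list", T_)
  bmat <- matrix(p$b, B, 3*u, byrow = TRUE)
  for (t in seq_len(T_)) {
    xt <- matrix(X[, t, ], B)
    a_in <- xt %*% p$W + bmat
    a_rec <- h %*% p$U
    zg <- .sigmoid(a_in[, z_ix, drop = FALSE] + a_rec[, z_ix, drop = FALSE])
    rg <- .sigmoid(a_in[, r_ix, drop = FALSE] + a_rec[, r_ix, drop = FALSE])
    rh <- rg * h
    hh <- tanh(a_in[, h_ix, drop = FALSE] + rh %*% p$U[, h_ix, drop = FALSE])
    h_prev <- h
    h <- zg * h_prev + (1 - zg) * hh
    H[, t, ] <- h
    cache[[t]] <- list(xt = xt, z = zg, r = rg, hh = hh, h_prev = h_prev,
                       rh = rh)
  }
  list(H = H, cache = cache, u = u)
}

.gru_backward <- function(p, fwd, dH, need_dx = FALSE) {
  cache <- fwd$cache; u <- fwd$u
  T_ <- length(cache); B <- nrow(cache[[1]]$xt)
  z_ix <- 1:u; r_ix <- u + z_ix; h_ix <- 2*u + z_ix
  dW <- 0 * p$W; dU <- 0 * p$U; db <- 0 * p$b
  dh <- matrix(0, B, u)
  dX <- if (need_dx) array(0, c(B, T_, nrow(p$W)))
  Uh <- p$U[, h_ix, drop = FALSE]
  for (t in rev(seq_len(T_))) {
    cc <- cache[[t]]
    dh <- dh + matrix(dH[, t, ], B)
    dz <- dh * (cc$h_prev - cc$hh)
    dhh <- dh * (1 - cc$z)
    dh_prev <- dh * cc$z
    dhh_pre <- dhh * (1 - cc$hh^2)
    dU[, h_ix] <- dU[, h_ix] + crossprod(cc$rh, dhh_pre)
    drh <- dhh_pre %*% t(Uh)
    dr <- drh * cc$h_prev
    dh_prev <- dh_prev + drh * cc$r
    dz_pre <- dz * cc$z * (1 - cc$z)
    dr_pre <- dr * cc$r * (1 - cc$r)
    dzr <- cbind(dz_pre, dr_pre)
    dW[, c(z_ix, r_ix)] <- dW[, c(z_ix, r_ix)] + crossprod(cc$xt, dzr)
    dW[, h_ix] <- dW[, h_ix] + crossprod(cc$xt, dhh_pre)
    dU[, c(z_ix, r_ix)] <- dU[, c(z_ix, r_ix)] + crossprod(cc$h_prev, dzr)
    db <- db + colSums(cbind(dzr, dhh_pre))
    dh_prev <- dh_prev + dzr %*% t(p$U[, c(z_ix, r_ix), drop = FALSE])
    dh <- dh_prev
    if (need_dx) {
      dX[, t, ] <- dzr %*% t(p$W[, c(z_ix, r_ix), drop = FALSE]) +
        dhh_pre %*% t(p$W[, h_ix, drop = FALSE])
    }
  }
  list(grads = list(W = dW, U = dU, b = db), dX = dX)
}

# ---- transformer pieces -------------------------------------------------

.positional_encoding <- function(T_, d) {
  pos <- 0:(T_ - 1)
  pe <- matrix(0, T_, d)
  for (j in seq_len(d)) {
    i2 <- (j - 1) %/% 2
    angle <- pos / 10000^(2 * i2 / d)
    pe[, j] <- if (j %% 2 == 1) sin(angle) else cos(angle)
  }
  pe
}

.layernorm_forward <- function(p, x, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat, 2L, p$g, "*")
  y <- sweep(y, 2L, p$b, "+")
  list(y = y, xhat = xhat, inv = inv)
}

.layernorm_backward <- function(p, cache, dy) {
  d <- ncol(dy)
  dxhat <- sweep(dy, 2L, p$g, "*")
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * cache$xhat)
  dx <- cache$inv / d * (d * dxhat - s1 - cache$xhat * s2)
  list(dx = dx,
       grads = list(g = colSums(dy * cache$xhat), b = colSums(dy)))
}

# x3: B x T x d array; single-head scaled dot-product self-attention
.attention_forward <- function(p, x3) {
  dims <- dim(x3); B <- dims[1]; T_ <- dims[2]; d <- dims[3]
  xm <- matrix(x3, B * T_, d)
  Q <- array(xm %*% p$Wq, dims)
  K <- array(xm %*% p$Wk, dims)
  V <- array(xm %*% p$Wv, dims)
  O <- array(0, dims)
  A <- vector("list", B)
  sc <- 1 / sqrt(d)
  for (b in seq_len(B)) {
    Qb <- matrix(Q[b, , ], T_); Kb <- matrix(K[b, , ], T_)
    S <- (Qb %*% t(Kb)) * sc
    S <- S - apply(S, 1L, max)
    E <- exp(S)
    Ab <- E / rowSums(E)
    O[b, , ] <- Ab %*% matrix(V[b, , ], T_)
    A[[b]] <- Ab
  }
  out <- array(matrix(O, B * T_, d) %*% p$Wo, dims)
  list(out = out, Q = Q, K = K, V = V, O = O, A = A, xm = xm)
}

.attention_backward <- function(p, cache, dout3) {
  dims <- dim(dout3); B <- dims[1]; T_ <- dims[2]; d <- dims[3]
  sc <- 1 / sqrt(d)
  doutm <- matrix(dout3, B * T_, d)
  dWo <- crossprod(matrix(cache$O, B * T_, d), doutm)
  dO <- array(doutm %*% t(p$Wo), dims)
  dQ <- array(0, dims); dK <- array(0, dims); dV <- array(0, dims)
  for (b in seq_len(B)) {
    dOb <- matrix(dO[b, , ], T_)
    Ab <- cache$A[[b]]
    Vb <- matrix(cache$V[b, , ], T_)
    dA <- dOb %*% t(Vb)
    dV[b, , ] <- crossprod(Ab, dOb)
    dS <- Ab * (dA - rowSums(Ab * dA))
    dQ[b, , ] <- (dS %*% matrix(cache$K[b, , ], T_)) * sc
    dK[b, , ] <- (crossprod(dS, matrix(cache$Q[b, , ], T_))) * sc
  }
  xm <- cache$xm
  dQm <- matrix(dQ, B * T_, d); dKm <- matrix(dK, B * T_, d)
  dVm <- matrix(dV, B * T_, d)
  dxm <- dQm %*% t(p$Wq) + dKm %*% t(p$Wk) + dVm %*% t(p$Wv)
  list(dx = array(dxm, dims),
       grads = list(Wq = crossprod(xm, dQm), Wk = crossprod(xm, dKm),
                    Wv = crossprod(xm, dVm), Wo = dWo))
}

.encoder_forward <- function(p, x3) {
  dims <- dim(x3); B <- dims[1]; T_ <- dims[2]; d <- dims[3]
  att <- .attention_forward(p, x3)
  res1 <- matrix(x3 + att$out, B * T_, d)
  ln1 <- .layernorm_forward(p$ln1, res1)
  f1 <- ln1$y %*% p$ff1$W
  f1 <- sweep(f1, 2L, p$ff1$b, "+")
  r1 <- pmax(f1, 0)
  f2 <- r1 %*% p$ff2$W
  f2 <- sweep(f2, 2L, p$ff2$b, "+")
  ln2 <- .layernorm_forward(p$ln2, ln1$y + f2)
  list(out = array(ln2$y, dims), att = att, ln1 = ln1, ln2 = ln2,
       r1 = r1, dims = dims)
}

.encoder_backward <- function(p, cache, dout3) {
  dims <- cache$dims; B <- dims[1]; T_ <- dims[2]; d <- dims[3]
  dy2 <- matrix(dout3, B * T_, d)
  bk2 <- .layernorm_backward(p$ln2, cache$ln2, dy2)
  dres2 <- bk2$dx                     # grad wrt (ln1.y + f2)
  dr1 <- dres2 %*% t(p$ff2$W)
  dW2 <- crossprod(cache$r1, dres2)
  db2 <- colSums(dres2)
  df1 <- dr1 * (cache$r1 > 0)
  dW1 <- crossprod(cache$ln1$y, df1)
  db1 <- colSums(df1)
  dln1y <- dres2 + df1 %*% t(p$ff1$W)
  bk1 <- .layernorm_backward(p$ln1, cache$ln1, dln1y)
  dres1 <- array(bk1$dx, dims)        # grad wrt (x + attention out)
  attb <- .attention_backward(p, cache$att, dres1)
  list(dx = dres1 + attb$dx,
       grads = list(Wq = attb$grads$Wq, Wk = attb$grads$Wk,
                    Wv = attb$grads$Wv, Wo = attb$grads$Wo,
                    ln1 = bk1$grads,
                    ff1 = list(W = dW1, b = db1),
                    ff2 = list(W = dW2, b = db2),
                    ln2 = bk2$grads))
}

# ---- full model forward/backward ---------------------------------------

# X: B x T x F; training toggles dropout (mask drawn from current RNG)
.nn_forward <- function(net, X, training = FALSE) {
  p <- net$params
  B <- dim(X)[1]
  if (net$arch %in% c("lstm", "gru")) {
    fw <- if (net$arch == "lstm") .lstm_forward else .gru_forward
    f1 <- fw(p$l1, X)
    f2 <- fw(p$l2, f1$H)
    feat <- matrix(f2$H[, dim(f2$H)[2], ], B)
    cache <- list(f1 = f1, f2 = f2)
  } else {
    T_ <- dim(X)[2]
    xm <- matrix(X, B * T_, dim(X)[3])
    emb <- xm %*% p$embed$W
    emb <- sweep(emb, 2L, p$embed$b, "+")
    pe <- .positional_encoding(T_, net$cfg$d_model)
    x3 <- array(emb, c(B, T_, net$cfg$d_model))
    for (t in seq_len(T_)) x3[, t, ] <- x3[, t, ] + rep(pe[t, ], each = B)
    e1 <- .encoder_forward(p$enc1, x3)
    e2 <- .encoder_forward(p$enc2, e1$out)
    feat <- matrix(e2$out[, dim(e2$out)[2], ], B)
    cache <- list(xm = xm, e1 = e1, e2 = e2, T_ = T_)
  }
  if (training && net$cfg$dropout > 0) {
    keep <- 1 - net$cfg$dropout
    mask <- matrix(rbinom(length(feat), 1, keep), nrow(feat)) / keep
    feat_d <- feat * mask
    cache$mask <- mask
  } else {
    feat_d <- feat
  }
  a1 <- feat_d %*% p$dense$W
  a1 <- sweep(a1, 2L, p$dense$b, "+")
  h1 <- pmax(a1, 0)
  y <- h1 %*% p$out$W
  y <- sweep(y, 2L, p$out$b, "+")
  cache$feat_d <- feat_d
  cache$h1 <- h1
  list(y = y, cache = cache)
}

.nn_backward <- function(net, X, fwd, dy) {
  p <- net$params
  cache <- fwd$cache
  B <- nrow(dy)
  g_out <- list(W = crossprod(cache$h1, dy), b = colSums(dy))
  dh1 <- dy %*% t(p$out$W)
  da1 <- dh1 * (cache$h1 > 0)
  g_dense <- list(W = crossprod(cache$feat_d, da1), b = colSums(da1))
  dfeat <- da1 %*% t(p$dense$W)
  if (!is.null(cache$mask)) dfeat <- dfeat * cache$mask
  if (net$arch %in% c("lstm", "gru")) {
    bw <- if (net$arch == "lstm") .lstm_backward else .gru_backward
    T_ <- dim(cache$f2$H)[2]
    dH2 <- array(0, dim(cache$f2$H))
    dH2[, T_, ] <- dfeat
    b2 <- bw(p$l2, cache$f2, dH2, need_dx = TRUE)
    b1 <- bw(p$l1, cache$f1, b2$dX, need_dx = FALSE)
    list(l1 = b1$grads, l2 = b2$grads, dense = g_dense, out = g_out)
  } else {
    T_ <- cache$T_
    d <- net$cfg$d_model
    dout2 <- array(0, c(B, T_, d))
    dout2[, T_, ] <- dfeat
    be2 <- .encoder_backward(p$enc2, cache$e2, dout2)
    be1 <- .encoder_backward(p$enc1, cache$e1, be2$dx)
    dembm <- matrix(be1$dx, B * T_, d)
    g_embed <- list(W = crossprod(cache$xm, dembm), b = colSums(dembm))
    list(embed = g_embed, enc1 = be1$grads, enc2 = be2$grads,
         dense = g_dense, out = g_out)
  }
}

# ---- Adam ---------------------------------------------------------------

.map_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- .map_params(a[[nm]], b[[nm]], f)
    out
  } else {
    f(a, b)
  }
}

.zeros_like <- function(p) .map_params(p, p, function(a, b) a * 0)

.adam_init <- function(params) {
  list(m = .zeros_like(params), v = .zeros_like(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  state$m <- .map_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- .map_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- .map_params(state$m, state$v, function(m, v) {
    lr * (m / bc1) / (sqrt(v / bc2) + eps)
  })
  params <- .map_params(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}

# flatten/unflatten helpers used by the gradient-check tests
.flatten_params <- function(p) {
  if (is.list(p)) unlist(lapply(p, .flatten_params), use.names = FALSE)
  else as.numeric(p)
}

.unflatten_params <- function(template, x) {
  pos <- 0L
  rec <- function(p) {
    if (is.list(p)) {
      for (nm in names(p)) p[[nm]] <- rec(p[[nm]])
      p
    } else {
      k <- length(p)
      out <- x[(pos + 1L):(pos + k)]
      pos <<- pos + k
      if (is.matrix(p)) matrix(out, nrow(p), ncol(p)) else out
    }
  }
  rec(template)
}
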