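# Minimal neural-network engine for sequence-to-activity models.
#
# Activations are stored as 3-D arrays [batch, position, channel];
# convolutions are evaluated as a single im2col matrix product per layer so
# all heavy arithmetic goes through BLAS gemm. Every layer implements an
# analytic backward pass (verified against finite differences in the test
# suite), both for weight gradients during SGD training and for input
# gradients during gradient-based sequence design.

.glorot <- function(fanIn, fanOut, dims) {
  lim <- sqrt(6 / (fanIn + fanOut))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

.layerConv <- function(k, pad, cin, cout) {
  W <- .glorot(k * cin, k * cout, c(k * cin, cout))
  list(type = "conv", k = k, pad = pad, cin = cin, cout = cout,
       W = matrix(W, k * cin, cout), b = numeric(cout))
}

.layerDense <- function(din, dout, act = "linear") {
  list(type = "dense", din = din, dout = dout, act = act,
       W = matrix(.glorot(din, dout, c(din, dout)), din, dout),
       b = numeric(dout))
}

# dense applied independently at every position of a [B,T,C] tensor
.layerTimeDense <- function(din, dout) {
  l <- .layerDense(din, dout)
  l$type <- "timedense"
  l
}

.layerLSTM <- function(cin, units, returnSeq) {
  list(type = "lstm", cin = cin, units = units, returnSeq = returnSeq,
       Wx = matrix(.glorot(cin, 4 * units, c(cin, 4 * units)), cin, 4 * units),
       Wh = matrix(.glorot(units, 4 * units, c(units, 4 * units)),
                   units, 4 * units),
       b = c(numeric(units), rep(1, units), numeric(2 * units)))
}

# --- layer forward/backward -------------------------------------------------

.im2col <- function(X, k, pad) {
  d <- dim(X); B <- d[1L]; L <- d[2L]; C <- d[3L]
  Xp <- array(0, c(B, L + 2L * pad, C))
  Xp[, pad + seq_len(L), ] <- X
  M <- matrix(0, B * L, k * C)
  for (j in seq_len(k))
    M[, (j - 1L) * C + seq_len(C)] <-
      matrix(Xp[, j:(j + L - 1L), , drop = FALSE], B * L, C)
  M
}

.col2im <- function(dM, B, L, C, k, pad) {
  dXp <- array(0, c(B, L + 2L * pad, C))
  for (j in seq_len(k))
    dXp[, j:(j + L - 1L), ] <- dXp[, j:(j + L - 1L), , drop = FALSE] +
      array(dM[, (j - 1L) * C + seq_len(C)], c(B, L, C))
  dXp[, pad + seq_len(L), , drop = FALSE]
}

.fwdConv <- function(layer, X) {
  d <- dim(X); B <- d[1L]; L <- d[2L]
  M <- .im2col(X, layer$k, layer$pad)
  Y <- M %*% layer$W
  Y <- sweep(Y, 2L, layer$b, "+")
  list(out = array(Y, c(B, L, layer$cout)), cache = list(M = M, dimX = d))
}

.bwdConv <- function(layer, cache, dY) {
  d <- cache$dimX
  dYm <- matrix(dY, d[1L] * d[2L], layer$cout)
  dW <- crossprod(cache$M, dYm)
  db <- colSums(dYm)
  dM <- tcrossprod(dYm, layer$W)
  dX <- .col2im(dM, d[1L], d[2L], d[3L], layer$k, layer$pad)
  list(grads = list(W = dW, b = db), dX = dX)
}

.fwdRelu <- function(X) {
  mask <- X > 0
  X[!mask] <- 0
  list(out = X, cache = mask)
}

.fwdPool2 <- function(X) {
  d <- dim(X); L2 <- d[2L] %/% 2L
  odd <- X[, 2L * seq_len(L2) - 1L, , drop = FALSE]
  even <- X[, 2L * seq_len(L2), , drop = FALSE]
  mask <- odd >= even        # ties take the earlier position
  list(out = pmax(odd, even), cache = list(mask = mask, dimX = d))
}

.bwdPool2 <- function(cache, dY) {
  d <- cache$dimX; L2 <- d[2L] %/% 2L
  dX <- array(0, d)
  dX[, 2L * seq_len(L2) - 1L, ] <- dY * cache$mask
  dX[, 2L * seq_len(L2), ] <- dY * !cache$mask
  dX
}

.fwdDense <- function(layer, X) {
  Y <- sweep(X %*% layer$W, 2L, layer$b, "+")
  pre <- Y
  if (layer$act == "relu") Y[Y < 0] <- 0
  list(out = Y, cache = list(X = X, pre = pre))
}

.bwdDense <- function(layer, cache, dY) {
  if (layer$act == "relu") dY <- dY * (cache$pre > 0)
  list(grads = list(W = crossprod(cache$X, dY), b = colSums(dY)),
       dX = tcrossprod(dY, layer$W))
}

.fwdTimeDense <- function(layer, X) {
  d <- dim(X)
  Xm <- matrix(aperm(X, c(1L, 2L, 3L)), d[1L] * d[2L], d[3L])
  f <- .fwdDense(layer, Xm)
  list(out = array(f$out, c(d[1L], d[2L], layer$dout)),
       cache = list(inner = f$cache, dimX = d))
}

.bwdTimeDense <- function(layer, cache, dY) {
  d <- cache$dimX
  b <- .bwdDense(layer, cache$inner,
                 matrix(dY, d[1L] * d[2L], layer$dout))
  list(grads = b$grads, dX = array(b$dX, d))
}

.sigm <- function(x) 1 / (1 + exp(-x))

.fwdLSTM <- function(layer, X) {
  d <- dim(X); B <- d[1L]; Tn <- d[2L]; U <- layer$units
  h <- matrix(0, B, U); cc <- matrix(0, B, U)
  steps <- vector("list", Tn)
  outs <- if (layer$returnSeq) array(0, c(B, Tn, U)) else NULL
  for (t in seq_len(Tn)) {
    xt <- matrix(X[, t, , drop = FALSE], B, layer$cin)
    z <- sweep(xt %*% layer$Wx + h %*% layer$Wh, 2L, layer$b, "+")
    i <- .sigm(z[, seq_len(U), drop = FALSE])
    f <- .sigm(z[, U + seq_len(U), drop = FALSE])
    g <- tanh(z[, 2L * U + seq_len(U), drop = FALSE])
    o <- .sigm(z[, 3L * U + seq_len(U), drop = FALSE])
    cPrev <- cc
    cc <- f * cPrev + i * g
    tc <- tanh(cc)
    hPrev <- h
    h <- o * tc
    steps[[t]] <- list(xt = xt, i = i, f = f, g = g, o = o,
                       cPrev = cPrev, cc = cc, tc = tc, hPrev = hPrev)
    if (layer$returnSeq) outs[, t, ] <- h
  }
  list(out = if (layer$returnSeq) outs else h,
       cache = list(steps = steps, dimX = d))
}

.bwdLSTM <- function(layer, cache, dY) {
  d <- cache$dimX; B <- d[1L]; Tn <- d[2L]; U <- layer$units
  dWx <- matrix(0, layer$cin, 4L * U); dWh <- matrix(0, U, 4L * U)
  db <- numeric(4L * U)
  dX <- array(0, d)
  dh <- matrix(0, B, U); dc <- matrix(0, B, U)
  for (t in rev(seq_len(Tn))) {
    s <- cache$steps[[t]]
    dht <- dh + if (layer$returnSeq) matrix(dY[, t, , drop = FALSE], B, U) else
      if (t == Tn) dY else matrix(0, B, U)
    do <- dht * s$tc
    dct <- dc + dht * s$o * (1 - s$tc^2)
    di <- dct * s$g
    dg <- dct * s$i
    df <- dct * s$cPrev
    dc <- dct * s$f
    dz <- cbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                dg * (1 - s$g^2),
                do * s$o * (1 - s$o))
    dWx <- dWx + crossprod(s$xt, dz)
    dWh <- dWh + crossprod(s$hPrev, dz)
    db <- db + colSums(dz)
    dX[, t, ] <- tcrossprod(dz, layer$Wx)
    dh <- tcrossprod(dz, layer$Wh)
  }
  list(grads = list(Wx = dWx, Wh = dWh, b = db), dX = dX)
}

# scaled dot-product self-attention; one dense produces the shared
# query/key projection, a second produces values
.fwdAttention <- function(X) {
  # X here is a list(qk, v): [B,T,D] each
  qk <- X$qk; v <- X$v
  d <- dim(qk); B <- d[1L]; Tn <- d[2L]; D <- d[3L]
  out <- array(0, c(B, Tn, D))
  caches <- vector("list", B)
  sc <- 1 / sqrt(D)
  for (bI in seq_len(B)) {
    Q <- matrix(qk[bI, , ], Tn, D)
    V <- matrix(v[bI, , ], Tn, D)
    S <- tcrossprod(Q) * sc
    S <- S - apply(S, 1L, max)
    A <- exp(S); A <- A / rowSums(A)
    out[bI, , ] <- A %*% V
    caches[[bI]] <- list(Q = Q, V = V, A = A)
  }
  list(out = out, cache = list(per = caches, sc = sc, dims = d))
}

.bwdAttention <- function(cache, dY) {
  d <- cache$dims; B <- d[1L]; Tn <- d[2L]; D <- d[3L]
  dqk <- array(0, d); dv <- array(0, d)
  for (bI in seq_len(B)) {
    cb <- cache$per[[bI]]
    dO <- matrix(dY[bI, , ], Tn, D)
    dA <- tcrossprod(dO, cb$V)
    dv[bI, , ] <- crossprod(cb$A, dO)
    # softmax backward, row-wise
    dS <- cb$A * (dA - rowSums(dA * cb$A))
    dS <- dS * cache$sc
    dqk[bI, , ] <- (dS + t(dS)) %*% cb$Q
  }
  list(dqk = dqk, dv = dv)
}
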