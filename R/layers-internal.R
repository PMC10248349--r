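# Internal differentiable layer primitives on H x W x C x N arrays.
# Each forward returns what its backward needs; backprop is hand-derived.

.conv <- function(x, w, b, k, pad) .convForward(x, w, b, k, k, pad)

.convBwd <- function(x, w, dy, k, pad) .convBackward(x, w, dy, k, k, pad)

# batch normalization over (H, W, N) per channel; biased variance
.bnF <- function(x, g, b, rm, rv, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); C <- d[3]
  xp <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(xp) <- c(d[1] * d[2] * d[4], C)
  if (training) {
    mu <- colMeans(xp)
    xc <- sweep(xp, 2L, mu)
    v <- colMeans(xc * xc)
    rm <- (1 - momentum) * rm + momentum * mu
    rv <- (1 - momentum) * rv + momentum * v
  } else {
    mu <- rm; v <- rv
    xc <- sweep(xp, 2L, mu)
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, istd, "*")
  y <- sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+")
  dim(y) <- c(d[1], d[2], d[4], d[3])
  list(y = aperm(y, c(1L, 2L, 4L, 3L)),
       cache = list(xhat = xhat, istd = istd, g = g, d = d, training = training),
       rm = rm, rv = rv)
}

.bnB <- function(dy, cache) {
  d <- cache$d; C <- d[3]
  dyp <- aperm(dy, c(1L, 2L, 4L, 3L))
  dim(dyp) <- c(d[1] * d[2] * d[4], C)
  xhat <- cache$xhat
  dg <- colSums(dyp * xhat)
  db <- colSums(dyp)
  dxhat <- sweep(dyp, 2L, cache$g, "*")
  if (cache$training) {
    m <- nrow(dyp)
    dx <- sweep(dxhat, 2L, colMeans(dxhat)) -
      sweep(xhat, 2L, colSums(dxhat * xhat) / m, "*")
    dx <- sweep(dx, 2L, cache$istd, "*")
  } else {
    dx <- sweep(dxhat, 2L, cache$istd, "*")
  }
  dim(dx) <- c(d[1], d[2], d[4], d[3])
  list(dx = aperm(dx, c(1L, 2L, 4L, 3L)), dg = dg, db = db)
}

.relu <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# clamped half-pixel-center bilinear x2 interpolation matrix (2n x n)
.bilinear2xMatrix <- function(n) {
  U <- matrix(0, 2L * n, n)
  for (i in seq_len(n)) {
    U[2L * i - 1L, i] <- U[2L * i - 1L, i] + 0.75
    U[2L * i - 1L, max(i - 1L, 1L)] <- U[2L * i - 1L, max(i - 1L, 1L)] + 0.25
    U[2L * i, i] <- U[2L * i, i] + 0.75
    U[2L * i, min(i + 1L, n)] <- U[2L * i, min(i + 1L, n)] + 0.25
  }
  U
}

.up2F <- function(x) {
  d <- dim(x)
  Ur <- .bilinear2xMatrix(d[1]); Uc <- .bilinear2xMatrix(d[2])
  y <- array(0, c(2L * d[1], 2L * d[2], d[3], d[4]))
  for (n in seq_len(d[4]))
    for (c in seq_len(d[3]))
      y[, , c, n] <- Ur %*% x[, , c, n] %*% t(Uc)
  y
}

.up2B <- function(dy, d) {
  Ur <- .bilinear2xMatrix(d[1]); Uc <- .bilinear2xMatrix(d[2])
  dx <- array(0, d)
  for (n in seq_len(d[4]))
    for (c in seq_len(d[3]))
      dx[, , c, n] <- t(Ur) %*% dy[, , c, n] %*% Uc
  dx
}

# 2x2 max pooling, stride 2; backward routes to the first maximum in the
# fixed order top-left, bottom-left, top-right, bottom-right
.maxpool2F <- function(x) {
  d <- dim(x)
  ro <- seq(1L, d[1], by = 2L); re <- seq(2L, d[1], by = 2L)
  co <- seq(1L, d[2], by = 2L); ce <- seq(2L, d[2], by = 2L)
  a <- x[ro, co, , , drop = FALSE]; b <- x[re, co, , , drop = FALSE]
  cc <- x[ro, ce, , , drop = FALSE]; dd <- x[re, ce, , , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  list(y = y, parts = list(a = a, b = b, c = cc, d = dd), d = d)
}

.maxpool2B <- function(dy, cache) {
  d <- cache$d
  p <- cache$parts
  y <- pmax(p$a, p$b, p$c, p$d)
  ma <- p$a == y
  mb <- (p$b == y) & !ma
  mc <- (p$c == y) & !(ma | mb)
  md <- !(ma | mb | mc)
  dx <- array(0, d)
  ro <- seq(1L, d[1], by = 2L); re <- seq(2L, d[1], by = 2L)
  co <- seq(1L, d[2], by = 2L); ce <- seq(2L, d[2], by = 2L)
  dx[ro, co, , ] <- dy * ma
  dx[re, co, , ] <- dy * mb
  dx[ro, ce, , ] <- dy * mc
  dx[re, ce, , ] <- dy * md
  dx
}

.catC <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  y
}
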