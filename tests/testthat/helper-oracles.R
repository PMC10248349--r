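# Independent brute-force oracles used to pin down the fast implementations.

# naive periodized 1D analysis: y_k = sum_i f_i x_{(2k+i) mod N}
oracleDwt1d <- function(x, f) {
  N <- length(x)
  vapply(seq_len(N %/% 2L), function(k) {
    s <- 0
    for (i in seq_along(f)) s <- s + f[i] * x[((2L * (k - 1L) + i - 1L) %% N) + 1L]
    s
  }, numeric(1))
}

# naive separable 2D decomposition of one matrix: rows first, then columns
oracleDwt2 <- function(m, l, h) {
  rowFilt <- function(mat, f) t(apply(mat, 1L, oracleDwt1d, f = f))
  colFilt <- function(mat, f) apply(mat, 2L, oracleDwt1d, f = f)
  L <- rowFilt(m, l); H <- rowFilt(m, h)
  list(ll = colFilt(L, l), lh = colFilt(H, l),
       hl = colFilt(L, h), hh = colFilt(H, h))
}

# per-pixel scalar-arithmetic attention gate (no normalization branch)
oracleRam <- function(xg, xl, params) {
  dg <- dim(xg); dl <- dim(xl)
  H <- dl[1]; W <- dl[2]; Cl <- dl[3]; Cg <- dg[3]
  Fint <- ncol(params$wg)
  alpha <- matrix(0, H, W)
  out <- array(0, dl)
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    s <- numeric(Fint)
    for (f in seq_len(Fint)) {
      acc <- params$wgB[f] + params$wlB[f]
      for (c in seq_len(Cg)) acc <- acc + xg[r, cc, c] * params$wg[c, f]
      for (c in seq_len(Cl)) acc <- acc + xl[r, cc, c] * params$wl[c, f]
      s[f] <- max(acc, 0)
    }
    z <- params$psiB[1]
    for (f in seq_len(Fint)) z <- z + s[f] * params$psi[f, 1]
    a <- 1 / (1 + exp(-z))
    alpha[r, cc] <- a
    for (c in seq_len(Cl)) out[r, cc, c] <- (1 + a) * xl[r, cc, c]
  }
  list(alpha = alpha, output = out)
}

# flood fill connectivity check (4-neighbourhood)
isConnected <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) <= 1L) return(TRUE)
  visited <- matrix(FALSE, nrow(mask), ncol(mask))
  queue <- list(idx[1, ])
  visited[idx[1, 1], idx[1, 2]] <- TRUE
  n <- 1L
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      q <- p + d
      if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 && q[2] <= ncol(mask) &&
          mask[q[1], q[2]] > 0 && !visited[q[1], q[2]]) {
        visited[q[1], q[2]] <- TRUE
        n <- n + 1L
        queue[[length(queue) + 1L]] <- q
      }
    }
  }
  n == nrow(idx)
}

# small random segmentation batch for network-level tests
testBatch <- function(h = 16L, w = 16L, c = 1L, n = 2L, seed = 1L) {
  set.seed(seed)
  list(x = array(runif(h * w * c * n), c(h, w, c, n)),
       y = array(rbinom(h * w * n, 1L, 0.3), c(h, w, 1L, n)))
}
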