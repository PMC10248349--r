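# Model assembly: 4-level encoder (conv block -> LL-wavelet downsample),
# bottleneck, 4-level decoder (bilinear upsample block -> attention-gated
# skip -> concatenation -> conv block), 1x1 sigmoid head.

#' Create a network configuration
#'
#' @param inChannels 1 (grayscale) or 3 (RGB).
#' @param baseChannels channels at the first encoder level; the reference
#'   configuration uses 64 (ladder 64/128/256/512, bottleneck 1024). Smaller
#'   values scale the whole ladder for desk-size experiments.
#' @param wavelet wavelet name, [WaveletSpec-class] or [WaveletFilterBank-class]
#'   used by all four downsampling stages.
#' @param downsample `"wavelet"` or `"maxpool"` (2x2 max-pooling ablation).
#' @param useRAM gate the skip connections through the residual attention
#'   module (`TRUE`) or pass them through untouched (`FALSE`, ablation).
#' @return a [WRANetConfig-class].
#' @examples
#' wranetConfig(baseChannels = 16, wavelet = "sym6")
#' @export
wranetConfig <- function(inChannels = 1L, baseChannels = 64L, wavelet = "haar",
                         downsample = c("wavelet", "maxpool"), useRAM = TRUE) {
  if (is.character(wavelet)) wavelet <- waveletSpec(wavelet)
  if (is(wavelet, "WaveletFilterBank")) wavelet <- wavelet@spec
  new("WRANetConfig",
      inChannels = as.integer(inChannels),
      baseChannels = as.integer(baseChannels),
      depth = 4L,
      wavelet = wavelet,
      downsample = match.arg(downsample),
      useRAM = isTRUE(useRAM))
}

# Kaiming-uniform init for a conv weight stored as (k*k*cin) x cout
.initConv <- function(k, cin, cout) {
  fanIn <- k * k * cin
  bound <- sqrt(6 / fanIn)
  list(w = matrix(runif(fanIn * cout, -bound, bound), fanIn, cout),
       b = runif(cout, -1 / sqrt(fanIn), 1 / sqrt(fanIn)))
}

# bias = FALSE for convolutions feeding batch normalization (a bias there is
# removed by the mean subtraction and would receive zero gradient)
.addConv <- function(P, pfx, k, cin, cout, bias = TRUE) {
  ini <- .initConv(k, cin, cout)
  P[[paste0(pfx, ".w")]] <- ini$w
  if (bias) P[[paste0(pfx, ".b")]] <- ini$b
  P
}

# conv through a parameter prefix; missing bias means zero
.convP <- function(x, P, pfx, k, pad) {
  w <- P[[paste0(pfx, ".w")]]
  b <- P[[paste0(pfx, ".b")]]
  if (is.null(b)) b <- numeric(ncol(w))
  .conv(x, w, b, k, pad)
}

.convBwdP <- function(x, dy, P, pfx, k, pad, G) {
  r <- .convBwd(x, P[[paste0(pfx, ".w")]], dy, k, pad)
  G[[paste0(pfx, ".w")]] <- r$dw
  if (!is.null(P[[paste0(pfx, ".b")]])) G[[paste0(pfx, ".b")]] <- r$db
  r$dx
}

.addBN <- function(P, S, pfx, c) {
  P[[paste0(pfx, ".g")]] <- rep(1, c)
  P[[paste0(pfx, ".b")]] <- rep(0, c)
  S[[paste0(pfx, ".rm")]] <- rep(0, c)
  S[[paste0(pfx, ".rv")]] <- rep(1, c)
  list(P = P, S = S)
}

#' Initialize a model
#'
#' Allocates all trainable parameters (Kaiming-uniform convolutions,
#' unit/zero batch-norm affine) and running statistics. Seed-controlled:
#' the same seed yields bitwise-identical parameters.
#'
#' @param config a [WRANetConfig-class].
#' @param seed integer RNG seed.
#' @return a [WRANetModel-class].
#' @examples
#' m <- wranetInit(wranetConfig(baseChannels = 4L), seed = 1)
#' numParameters(m)
#' @export
wranetInit <- function(config, seed = 1L) {
  stopifnot(is(config, "WRANetConfig"))
  validObject(config)
  set.seed(as.integer(seed))
  B <- config@baseChannels
  ch <- B * c(1L, 2L, 4L, 8L, 16L)     # level channels + bottleneck
  P <- list(); S <- list()
  addBlock <- function(pfx, cin, cout) {
    P <<- .addConv(P, paste0(pfx, ".conv1"), 3L, cin, cout, bias = FALSE)
    r <- .addBN(P, S, paste0(pfx, ".bn1"), cout); P <<- r$P; S <<- r$S
    P <<- .addConv(P, paste0(pfx, ".conv2"), 3L, cout, cout, bias = FALSE)
    r <- .addBN(P, S, paste0(pfx, ".bn2"), cout); P <<- r$P; S <<- r$S
  }
  cin <- config@inChannels
  for (k in 1:4) { addBlock(paste0("enc", k), cin, ch[k]); cin <- ch[k] }
  addBlock("bott", ch[4], ch[5])
  for (k in 4:1) {
    # upsample block: 3x3 conv halving channels after bilinear x2
    P <- .addConv(P, paste0("up", k, ".conv"), 3L, ch[k + 1L], ch[k], bias = FALSE)
    r <- .addBN(P, S, paste0("up", k, ".bn"), ch[k]); P <- r$P; S <- r$S
    if (config@useRAM) {
      C <- ch[k]   # intermediate channel count F_int = channels at this level
      P <- .addConv(P, paste0("ram", k, ".wg"), 1L, C, C, bias = FALSE)
      r <- .addBN(P, S, paste0("ram", k, ".bng"), C); P <- r$P; S <- r$S
      P <- .addConv(P, paste0("ram", k, ".wl"), 1L, C, C, bias = FALSE)
      r <- .addBN(P, S, paste0("ram", k, ".bnl"), C); P <- r$P; S <- r$S
      P <- .addConv(P, paste0("ram", k, ".psi"), 1L, C, 1L)
    }
    addBlock(paste0("dec", k), 2L * ch[k], ch[k])
  }
  P <- .addConv(P, "head", 1L, ch[1], 1L)
  new("WRANetModel", config = config, params = P,
      state = c(S, list(version = as.character(utils::packageVersion("wranet")))))
}

#' Number of trainable parameters
#'
#' Invariant to the wavelet choice: the DWT downsampling is parameter-free.
#'
#' @param model a [WRANetModel-class].
#' @return integer count of scalar parameters.
#' @export
numParameters <- function(model) {
  sum(vapply(model@params, length, integer(1)))
}

# conv block: two (3x3 conv -> BN -> ReLU) stages
.blockF <- function(x, pfx, P, S, training) {
  c1 <- .convP(x, P, paste0(pfx, ".conv1"), 3L, 1L)
  b1 <- .bnF(c1, P[[paste0(pfx, ".bn1.g")]], P[[paste0(pfx, ".bn1.b")]],
             S[[paste0(pfx, ".bn1.rm")]], S[[paste0(pfx, ".bn1.rv")]], training)
  S[[paste0(pfx, ".bn1.rm")]] <- b1$rm; S[[paste0(pfx, ".bn1.rv")]] <- b1$rv
  r1 <- .relu(b1$y)
  c2 <- .convP(r1$y, P, paste0(pfx, ".conv2"), 3L, 1L)
  b2 <- .bnF(c2, P[[paste0(pfx, ".bn2.g")]], P[[paste0(pfx, ".bn2.b")]],
             S[[paste0(pfx, ".bn2.rm")]], S[[paste0(pfx, ".bn2.rv")]], training)
  S[[paste0(pfx, ".bn2.rm")]] <- b2$rm; S[[paste0(pfx, ".bn2.rv")]] <- b2$rv
  r2 <- .relu(b2$y)
  list(y = r2$y, S = S,
       cache = list(x = x, bn1 = b1$cache, m1 = r1$mask, h1 = r1$y,
                    bn2 = b2$cache, m2 = r2$mask))
}

.blockB <- function(dy, pfx, P, cache, G) {
  dy <- dy * cache$m2
  b2 <- .bnB(dy, cache$bn2)
  G[[paste0(pfx, ".bn2.g")]] <- b2$dg; G[[paste0(pfx, ".bn2.b")]] <- b2$db
  dh1 <- .convBwdP(cache$h1, b2$dx, P, paste0(pfx, ".conv2"), 3L, 1L, G) * cache$m1
  b1 <- .bnB(dh1, cache$bn1)
  G[[paste0(pfx, ".bn1.g")]] <- b1$dg; G[[paste0(pfx, ".bn1.b")]] <- b1$db
  .convBwdP(cache$x, b1$dx, P, paste0(pfx, ".conv1"), 3L, 1L, G)
}

# residual attention gate: alpha = sigmoid(psi(relu(BN(Wg g) + BN(Wl l))));
# output (1 + alpha) * l with alpha broadcast over channels
.ramF <- function(g, l, pfx, P, S, training) {
  qg <- .convP(g, P, paste0(pfx, ".wg"), 1L, 0L)
  bg <- .bnF(qg, P[[paste0(pfx, ".bng.g")]], P[[paste0(pfx, ".bng.b")]],
             S[[paste0(pfx, ".bng.rm")]], S[[paste0(pfx, ".bng.rv")]], training)
  S[[paste0(pfx, ".bng.rm")]] <- bg$rm; S[[paste0(pfx, ".bng.rv")]] <- bg$rv
  ql <- .convP(l, P, paste0(pfx, ".wl"), 1L, 0L)
  bl <- .bnF(ql, P[[paste0(pfx, ".bnl.g")]], P[[paste0(pfx, ".bnl.b")]],
             S[[paste0(pfx, ".bnl.rm")]], S[[paste0(pfx, ".bnl.rv")]], training)
  S[[paste0(pfx, ".bnl.rm")]] <- bl$rm; S[[paste0(pfx, ".bnl.rv")]] <- bl$rv
  r <- .relu(bg$y + bl$y)
  z <- .convP(r$y, P, paste0(pfx, ".psi"), 1L, 0L)
  a <- .sigmoid(z)
  C <- dim(l)[3]
  ab <- a[, , rep(1L, C), , drop = FALSE]
  list(y = l * (1 + ab), alpha = a, S = S,
       cache = list(g = g, l = l, bng = bg$cache, bnl = bl$cache,
                    mask = r$mask, s = r$y, a = a, C = C))
}

.ramB <- function(dy, pfx, P, cache, G) {
  C <- cache$C
  a <- cache$a
  ab <- a[, , rep(1L, C), , drop = FALSE]
  dl <- dy * (1 + ab)
  da <- dy * cache$l
  da <- array(rowSums(aperm(da, c(1L, 2L, 4L, 3L)), dims = 3L),
              dim(a)[c(1L, 2L, 4L)])         # sum over channels
  da <- aperm(array(da, c(dim(a)[1:2], dim(a)[4], 1L)), c(1L, 2L, 4L, 3L))
  dz <- da * a * (1 - a)
  ds <- .convBwdP(cache$s, dz, P, paste0(pfx, ".psi"), 1L, 0L, G) * cache$mask
  bg <- .bnB(ds, cache$bng)
  G[[paste0(pfx, ".bng.g")]] <- bg$dg; G[[paste0(pfx, ".bng.b")]] <- bg$db
  dgOut <- .convBwdP(cache$g, bg$dx, P, paste0(pfx, ".wg"), 1L, 0L, G)
  bl <- .bnB(ds, cache$bnl)
  G[[paste0(pfx, ".bnl.g")]] <- bl$dg; G[[paste0(pfx, ".bnl.b")]] <- bl$db
  dlOut <- .convBwdP(cache$l, bl$dx, P, paste0(pfx, ".wl"), 1L, 0L, G)
  list(dg = dgOut, dl = dl + dlOut)
}

.downF <- function(x, config, bank) {
  if (config@downsample == "wavelet") {
    list(y = .colPass(.rowPass(x, bank@analysisLow), bank@analysisLow),
         cache = list(kind = "wavelet", d = dim(x)))
  } else {
    mp <- .maxpool2F(x)
    list(y = mp$y, cache = c(mp["parts"], list(kind = "maxpool", d = dim(x))))
  }
}

.downB <- function(dy, cache, bank) {
  if (cache$kind == "wavelet") {
    .waveletDownsampleBackward(dy, bank, cache$d[1], cache$d[2])
  } else {
    .maxpool2B(dy, list(parts = cache$parts, d = cache$d))
  }
}

# full forward pass; returns probabilities and (optionally) every cache
# needed for the backward sweep
.netForward <- function(P, S, x, config, training = FALSE, withCache = FALSE) {
  bank <- buildFilterBank(config@wavelet)
  caches <- list()
  skips <- list()
  h <- x
  for (k in 1:4) {
    bl <- .blockF(h, paste0("enc", k), P, S, training); S <- bl$S
    skips[[k]] <- bl$y
    dn <- .downF(bl$y, config, bank)
    h <- dn$y
    if (withCache) caches[[paste0("enc", k)]] <- list(block = bl$cache, down = dn$cache)
  }
  bl <- .blockF(h, "bott", P, S, training); S <- bl$S
  h <- bl$y
  if (withCache) caches[["bott"]] <- bl$cache
  for (k in 4:1) {
    dIn <- dim(h)
    u <- .up2F(h)
    cu <- .convP(u, P, paste0("up", k, ".conv"), 3L, 1L)
    bu <- .bnF(cu, P[[paste0("up", k, ".bn.g")]], P[[paste0("up", k, ".bn.b")]],
               S[[paste0("up", k, ".bn.rm")]], S[[paste0("up", k, ".bn.rv")]], training)
    S[[paste0("up", k, ".bn.rm")]] <- bu$rm; S[[paste0("up", k, ".bn.rv")]] <- bu$rv
    ru <- .relu(bu$y)
    g <- ru$y
    if (config@useRAM) {
      ram <- .ramF(g, skips[[k]], paste0("ram", k), P, S, training); S <- ram$S
      gated <- ram$y
    } else {
      ram <- NULL
      gated <- skips[[k]]
    }
    hcat <- .catC(gated, g)
    bl <- .blockF(hcat, paste0("dec", k), P, S, training); S <- bl$S
    if (withCache)
      caches[[paste0("dec", k)]] <- list(
        dIn = dIn, u = u, bn = bu$cache, mask = ru$mask, g = g,
        ram = if (!is.null(ram)) ram$cache, block = bl$cache,
        nGated = dim(gated)[3])
    h <- bl$y
  }
  z <- .convP(h, P, "head", 1L, 0L)
  p <- .sigmoid(z)
  if (withCache) caches[["head"]] <- list(x = h, p = p)
  list(p = p, S = S, caches = if (withCache) caches)
}

# backward sweep from dL/dp; returns gradient list matching names(P)
.netBackward <- function(P, config, caches, dp) {
  bank <- buildFilterBank(config@wavelet)
  G <- new.env(parent = emptyenv())
  hc <- caches[["head"]]
  dz <- dp * hc$p * (1 - hc$p)
  dh <- .convBwdP(hc$x, dz, P, "head", 1L, 0L, G)
  dskips <- vector("list", 4L)
  for (k in 1:4) {
    cc <- caches[[paste0("dec", k)]]
    dcat <- .blockB(dh, paste0("dec", k), P, cc$block, G)
    nG <- cc$nGated
    dGated <- dcat[, , seq_len(nG), , drop = FALSE]
    dg <- dcat[, , nG + seq_len(dim(dcat)[3] - nG), , drop = FALSE]
    if (config@useRAM) {
      rb <- .ramB(dGated, paste0("ram", k), P, cc$ram, G)
      dskips[[k]] <- rb$dl
      dg <- dg + rb$dg
    } else {
      dskips[[k]] <- dGated
    }
    dg <- dg * cc$mask
    bu <- .bnB(dg, cc$bn)
    G[[paste0("up", k, ".bn.g")]] <- bu$dg; G[[paste0("up", k, ".bn.b")]] <- bu$db
    dh <- .up2B(.convBwdP(cc$u, bu$dx, P, paste0("up", k, ".conv"), 3L, 1L, G), cc$dIn)
  }
  dh <- .blockB(dh, "bott", P, caches[["bott"]], G)
  for (k in 4:1) {
    cc <- caches[[paste0("enc", k)]]
    dskip <- .downB(dh, cc$down, bank) + dskips[[k]]
    dh <- .blockB(dskip, paste0("enc", k), P, cc$block, G)
  }
  grads <- as.list(G)
  grads[names(P)]
}

#' Run a model on images
#'
#' Evaluates the network in inference mode (batch normalization uses running
#' statistics) and returns per-pixel foreground probabilities.
#'
#' @param model a [WRANetModel-class].
#' @param x image(s): `H x W`, `H x W x C`, or a batch `H x W x C x N`; `H`
#'   and `W` must be divisible by `2^depth` (16).
#' @return probability array in `(0, 1)`, shape `H x W (x 1 (x N))`
#'   following the rank of the input.
#' @examples
#' m <- wranetInit(wranetConfig(baseChannels = 2L), seed = 1)
#' p <- wranetForward(m, array(runif(32 * 32), c(32, 32, 1)))
#' range(p)
#' @export
wranetForward <- function(model, x) {
  stopifnot(is(model, "WRANetModel"))
  g <- .as4d(x)
  d <- dim(g$x)
  div <- 2L^model@config@depth
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop(sprintf("input spatial size %d x %d must be divisible by %d", d[1], d[2], div))
  if (d[3] != model@config@inChannels)
    stop(sprintf("input has %d channels; model expects %d", d[3], model@config@inChannels))
  out <- .netForward(model@params, model@state, g$x, model@config,
                     training = FALSE, withCache = FALSE)
  .restoreRank(out$p, g$rank)
}

setMethod("show", "WRANetConfig", function(object) {
  B <- object@baseChannels
  cat(sprintf("WRANetConfig: in=%d, ladder %s (bottleneck %d), wavelet=%s, downsample=%s, RAM=%s\n",
              object@inChannels, paste(B * c(1, 2, 4, 8), collapse = "/"),
              16L * B, waveletName(object@wavelet), object@downsample,
              object@useRAM))
})

setMethod("show", "WRANetModel", function(object) {
  show(object@config)
  cat(sprintf("WRANetModel with %s trainable parameters\n",
              format(numParameters(object), big.mark = ",")))
})
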