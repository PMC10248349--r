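test_that("conv blocks preserve spatial size and map zero to zero", {
  cfg <- wranetConfig(inChannels = 1L, baseChannels = 4L)
  m <- wranetInit(cfg, seed = 1)
  x <- array(rnorm(16 * 16 * 1 * 2), c(16, 16, 1, 2))
  bl <- wranet:::.blockF(x, "enc1", m@params, m@state, training = FALSE)
  expect_equal(dim(bl$y), c(16L, 16L, 4L, 2L))
  # zero input through bias-free conv + identity-affine BN + ReLU stays zero
  z <- wranet:::.blockF(array(0, c(16, 16, 1, 2)), "enc1", m@params, m@state,
                        training = FALSE)
  expect_equal(max(abs(z$y)), 0)
})

test_that("the bilinear upsample stage matches a hand-rolled interpolation oracle", {
  set.seed(1)
  x <- array(rnorm(6 * 6 * 2 * 1), c(6, 6, 2, 1))
  y <- wranet:::.up2F(x)
  expect_equal(dim(y), c(12L, 6L * 2L, 2L, 1L))
  # independent oracle: half-pixel centers, clamped edges, per output pixel
  for (ch in 1:2) for (r in 1:12) for (cc in 1:12) {
    sr <- (r - 0.5) / 2 - 0.5 + 1    # 1-based source coordinate
    sc <- (cc - 0.5) / 2 - 0.5 + 1
    r0 <- floor(sr); c0 <- floor(sc)
    wr <- sr - r0; wc <- sc - c0
    cl <- function(v) min(max(v, 1), 6)
    val <- (1 - wr) * (1 - wc) * x[cl(r0), cl(c0), ch, 1] +
           (1 - wr) * wc * x[cl(r0), cl(c0 + 1), ch, 1] +
           wr * (1 - wc) * x[cl(r0 + 1), cl(c0), ch, 1] +
           wr * wc * x[cl(r0 + 1), cl(c0 + 1), ch, 1]
    expect_equal(y[r, cc, ch, 1], val, tolerance = 1e-12)
  }
  # constant maps to constant exactly
  k <- wranet:::.up2F(array(3.25, c(4, 4, 1, 1)))
  expect_equal(range(k), c(3.25, 3.25))
})

test_that("the upsample block doubles spatial size and halves channels", {
  cfg <- wranetConfig(inChannels = 1L, baseChannels = 4L)
  m <- wranetInit(cfg, seed = 1)
  # bottleneck channels 64 -> level-4 channels 32 at doubled resolution
  h <- array(rnorm(2 * 2 * 64), c(2, 2, 64, 1))
  u <- wranet:::.up2F(h)
  cu <- wranet:::.convP(u, m@params, "up4.conv", 3L, 1L)
  expect_equal(dim(cu), c(4L, 4L, 32L, 1L))
})

test_that("the forward pass preserves spatial size and outputs probabilities", {
  cfg <- wranetConfig(inChannels = 3L, baseChannels = 4L, wavelet = "db2")
  m <- wranetInit(cfg, seed = 2)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  p <- wranetForward(m, x)
  expect_equal(dim(p), c(64L, 64L, 1L))
  expect_gt(min(p), 0)
  expect_lt(max(p), 1)
  # rectangular input
  x2 <- array(runif(32 * 48 * 3 * 2), c(32, 48, 3, 2))
  expect_equal(dim(wranetForward(m, x2)), c(32L, 48L, 1L, 2L))
})

test_that("inference is deterministic", {
  cfg <- wranetConfig(inChannels = 1L, baseChannels = 2L, wavelet = "sym2")
  m <- wranetInit(cfg, seed = 3)
  x <- array(runif(32 * 32), c(32, 32, 1))
  expect_identical(wranetForward(m, x), wranetForward(m, x))
})

test_that("invalid input sizes and channel counts raise informative errors", {
  m <- wranetInit(wranetConfig(inChannels = 1L, baseChannels = 2L), seed = 1)
  expect_error(wranetForward(m, array(0, c(24, 24, 1))), "divisible by 16")
  expect_error(wranetForward(m, array(0, c(32, 32, 3))), "channels")
})

test_that("analytic gradients match finite differences through the whole net", {
  cfg <- wranetConfig(inChannels = 1L, baseChannels = 2L, wavelet = "haar")
  m <- wranetInit(cfg, seed = 3)
  P <- m@params; S <- m@state
  b <- testBatch(16L, 16L, 1L, 2L, seed = 42)
  lc <- lossConfig()
  fw <- wranet:::.netForward(P, S, b$x, cfg, training = TRUE, withCache = TRUE)
  lg <- wranet:::.lossWithGrad(fw$p, b$y, lc, "hybrid")
  G <- wranet:::.netBackward(P, cfg, fw$caches, array(lg$grad, dim(fw$p)))
  lossAt <- function(P2) {
    f <- wranet:::.netForward(P2, S, b$x, cfg, training = TRUE)
    wranet:::.lossWithGrad(f$p, b$y, lc, "hybrid")$loss
  }
  eps <- 1e-5
  set.seed(7)
  for (nm in c("enc2.conv1.w", "ram3.psi.w", "up2.conv.w", "dec1.bn2.g", "head.b")) {
    i <- sample(length(P[[nm]]), 1)
    Pp <- P; Pp[[nm]][i] <- Pp[[nm]][i] + eps
    Pm <- P; Pm[[nm]][i] <- Pm[[nm]][i] - eps
    num <- (lossAt(Pp) - lossAt(Pm)) / (2 * eps)
    expect_equal(G[[nm]][i], num, tolerance = 1e-4, label = nm)
  }
})

test_that("every trainable parameter receives gradient from a BCE loss", {
  cfg <- wranetConfig(inChannels = 1L, baseChannels = 2L, wavelet = "sym2")
  m <- wranetInit(cfg, seed = 5)
  b <- testBatch(16L, 16L, 1L, 2L, seed = 11)
  fw <- wranet:::.netForward(m@params, m@state, b$x, cfg, training = TRUE,
                             withCache = TRUE)
  lg <- wranet:::.lossWithGrad(fw$p, b$y, lossConfig(), "bce")
  G <- wranet:::.netBackward(m@params, cfg, fw$caches, array(lg$grad, dim(fw$p)))
  expect_setequal(names(G), names(m@params))
  for (nm in names(G))
    expect_gt(max(abs(G[[nm]])), 0, label = nm)
})

test_that("the parameter count is invariant to the wavelet and downsampler", {
  counts <- vapply(c("haar", "db5", "sym6", "bior2.2", "rbio4.4"), function(w)
    numParameters(wranetInit(wranetConfig(baseChannels = 4L, wavelet = w), seed = 1)),
    numeric(1))
  expect_equal(length(unique(counts)), 1L)
  mp <- wranetInit(wranetConfig(baseChannels = 4L, downsample = "maxpool"), seed = 1)
  expect_equal(unname(counts[1]), numParameters(mp))
})

test_that("max-pooling ablation keeps all shape contracts", {
  cfg <- wranetConfig(inChannels = 1L, baseChannels = 2L, downsample = "maxpool")
  m <- wranetInit(cfg, seed = 6)
  x <- array(runif(48 * 32), c(48, 32, 1))
  p <- wranetForward(m, x)
  expect_equal(dim(p), c(48L, 32L, 1L))
  # and gradients still flow everywhere
  b <- testBatch(16L, 16L, 1L, 2L, seed = 12)
  fw <- wranet:::.netForward(m@params, m@state, b$x, cfg, training = TRUE,
                             withCache = TRUE)
  lg <- wranet:::.lossWithGrad(fw$p, b$y, lossConfig(), "hybrid")
  G <- wranet:::.netBackward(m@params, cfg, fw$caches, array(lg$grad, dim(fw$p)))
  for (nm in names(G))
    expect_gt(max(abs(G[[nm]])), 0, label = nm)
})

test_that("disabling the attention gates removes their parameters only", {
  withRam <- wranetInit(wranetConfig(baseChannels = 4L), seed = 1)
  noRam <- wranetInit(wranetConfig(baseChannels = 4L, useRAM = FALSE), seed = 1)
  ramParams <- grep("^ram", names(withRam@params), value = TRUE)
  expect_gt(length(ramParams), 0)
  expect_equal(setdiff(names(withRam@params), names(noRam@params)), ramParams)
  x <- array(runif(32 * 32), c(32, 32, 1))
  expect_equal(dim(wranetForward(noRam, x)), c(32L, 32L, 1L))
})

test_that("max pooling layer and its backward route are exact", {
  set.seed(13)
  x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  f <- wranet:::.maxpool2F(x)
  expect_equal(dim(f$y), c(4L, 4L, 2L, 2L))
  # forward equals a plain loop maximum
  for (r in 1:4) for (cc in 1:4)
    expect_equal(f$y[r, cc, 1, 1],
                 max(x[(2 * r - 1):(2 * r), (2 * cc - 1):(2 * cc), 1, 1]))
  dy <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  dx <- wranet:::.maxpool2B(dy, f)
  # gradient mass is conserved and lands only on maxima
  expect_equal(sum(dx), sum(dy))
  expect_equal(sum(dx != 0), 4 * 4 * 2 * 2)
})
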