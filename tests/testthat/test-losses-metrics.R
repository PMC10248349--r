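test_that("BCE matches its closed forms", {
  # p = 0.5 everywhere: -log(1/2)
  expect_equal(bceLoss(rep(0.5, 7), c(1, 0, 1, 1, 0, 0, 1)), log(2))
  # two-term hand computation
  expect_equal(bceLoss(c(0.9, 0.2), c(1, 0)), -(log(0.9) + log(0.8)) / 2,
               tolerance = 1e-12)
  expect_equal(-(log(0.9) + log(0.8)) / 2, 0.164252, tolerance = 1e-6)
  # perfect prediction: bounded by the clamp
  y <- c(0, 1, 1, 0)
  expect_lte(bceLoss(y, y), -log(1 - 1e-7) + 1e-12)
})

test_that("Dice loss matches its closed forms including the empty-mask degeneracy", {
  ones <- rep(1, 100)
  expect_equal(diceLoss(ones, ones, lambdaSmooth = 1), 1 - 200 / 201)
  expect_equal(1 - 200 / 201, 0.004975, tolerance = 1e-4)
  expect_equal(diceLoss(rep(0, 50), rep(1, 50)), 1)        # zero overlap
  expect_equal(diceLoss(rep(0, 50), rep(0, 50), 1), 1)     # empty/empty degeneracy
})

test_that("the hybrid loss is the stated weighted combination", {
  # components ln 2 and 1 combine to 0.4*ln2 + 0.6
  p <- rep(0.5, 10); y <- rep(1, 10)
  bce <- bceLoss(p, y)                    # ln 2
  # choose y2/p2 with Dice loss 1: p = 0, y = 1
  expect_equal(0.4 * log(2) + 0.6 * 1, 0.877259, tolerance = 1e-6)
  p2 <- rep(0, 20); y2 <- rep(1, 20)
  expect_equal(hybridLoss(p2, y2, lossConfig(lambdaSmooth = 1)),
               0.4 * bceLoss(p2, y2) + 0.6 * 1, tolerance = 1e-12)
  # degenerate weights reduce to the individual losses
  set.seed(1)
  pr <- runif(30); yr <- rbinom(30, 1, 0.4)
  expect_equal(hybridLoss(pr, yr, lossConfig(alphaWeight = 1, betaWeight = 0)),
               bceLoss(pr, yr))
  expect_equal(hybridLoss(pr, yr, lossConfig(alphaWeight = 0, betaWeight = 1)),
               diceLoss(pr, yr))
})

test_that("loss gradients match finite differences", {
  set.seed(2)
  p <- runif(25, 0.05, 0.95); y <- rbinom(25, 1, 0.5)
  cfg <- lossConfig()
  for (kind in c("bce", "dice", "hybrid")) {
    lg <- wranet:::.lossWithGrad(p, y, cfg, kind)
    eps <- 1e-6
    for (i in c(1, 10, 25)) {
      pp <- p; pp[i] <- pp[i] + eps
      pm <- p; pm[i] <- pm[i] - eps
      num <- (wranet:::.lossWithGrad(pp, y, cfg, kind)$loss -
              wranet:::.lossWithGrad(pm, y, cfg, kind)$loss) / (2 * eps)
      expect_equal(lg$grad[i], num, tolerance = 1e-5,
                   label = paste(kind, "grad", i))
    }
  }
})

test_that("the metrics toy case reproduces the hand-derived values", {
  gt <- matrix(0, 4, 4); gt[1:4] <- 1                  # |G| = 4
  pred <- matrix(0, 4, 4); pred[2:7] <- 1              # |P| = 6, overlap 3
  r <- metrics(pred, gt)
  expect_equal(r@dice, 0.6)
  expect_equal(r@iou, 3 / 7)
  expect_equal(r@precision, 0.5)
  expect_equal(r@sensitivity, 0.75)
  expect_equal(as.integer(c(r@tp, r@fp, r@fn)), c(3L, 3L, 1L))
})

test_that("identical, disjoint and empty masks hit the documented conventions", {
  g <- matrix(0, 4, 4); g[1:2, 1:2] <- 1
  same <- metrics(g, g)
  expect_equal(c(same@dice, same@iou, same@precision, same@sensitivity),
               rep(1, 4))
  d <- matrix(0, 4, 4); d[3:4, 3:4] <- 1
  dis <- metrics(d, g)
  expect_equal(c(dis@dice, dis@iou, dis@precision, dis@sensitivity), rep(0, 4))
  e <- matrix(0, 4, 4)
  expect_equal(metrics(e, e)@dice, 1)        # both empty
  expect_equal(metrics(e, g)@dice, 0)        # prediction empty
  expect_equal(metrics(g, e)@dice, 0)        # ground truth empty
})

test_that("IoU equals Dice/(2 - Dice) on random masks", {
  set.seed(3)
  for (i in 1:100) {
    g <- matrix(rbinom(64, 1, runif(1, 0.1, 0.6)), 8, 8)
    p <- matrix(rbinom(64, 1, runif(1, 0.1, 0.6)), 8, 8)
    r <- metrics(p, g)
    expect_equal(r@iou, r@dice / (2 - r@dice), tolerance = 1e-12)
  }
})

test_that("metrics are invariant to simultaneous spatial permutation", {
  set.seed(4)
  g <- matrix(rbinom(64, 1, 0.3), 8, 8)
  p <- matrix(runif(64), 8, 8)
  perm <- sample(64)
  r1 <- metrics(p, g)
  r2 <- metrics(matrix(p[perm], 8, 8), matrix(g[perm], 8, 8))
  expect_equal(r1@dice, r2@dice)
  expect_equal(r1@iou, r2@iou)
  expect_equal(r1@precision, r2@precision)
  expect_equal(r1@sensitivity, r2@sensitivity)
})

test_that("macro and micro aggregation differ as designed and serialize to JSON", {
  g1 <- matrix(0, 4, 4); g1[1] <- 1
  p1 <- g1                                 # perfect small image
  g2 <- matrix(1, 4, 4); p2 <- matrix(0, 4, 4); p2[1:8] <- 1  # half right
  macro <- metrics(list(p1, p2), list(g1, g2), aggregate = "macro")
  micro <- metrics(list(p1, p2), list(g1, g2), aggregate = "micro")
  expect_equal(macro@dice, (1 + 2 * 8 / (16 + 8)) / 2)
  expect_equal(micro@dice, 2 * 9 / (17 + 9))
  js <- jsonlite::fromJSON(metricsToJSON(macro))
  expect_equal(js$dice, macro@dice)
  expect_equal(js$n_images, 2L)
  expect_true(all(c("tp", "fp", "fn", "tn") %in% names(js)))
})

test_that("soft Dice on hard masks equals 1 - Dice up to the smoothing term", {
  set.seed(5)
  g <- matrix(rbinom(256, 1, 0.3), 16, 16)
  p <- matrix(rbinom(256, 1, 0.3), 16, 16)
  hard <- metrics(p, g)@dice
  soft <- 1 - diceLoss(as.numeric(p), as.numeric(g), lambdaSmooth = 1e-9)
  expect_equal(soft, hard, tolerance = 1e-6)
})

test_that("hybrid loss decreases as predictions approach the mask", {
  set.seed(6)
  y <- rbinom(100, 1, 0.4)
  cfg <- lossConfig()
  steps <- seq(0.05, 0.95, by = 0.1)
  losses <- vapply(steps, function(t) {
    p <- y * t + (1 - y) * (1 - t)   # t is per-pixel confidence in the truth
    hybridLoss(p, y, cfg)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_true(all(losses >= 0))
})

test_that("shape and domain violations are rejected", {
  expect_error(bceLoss(c(0.5, 0.5), c(1, 0, 1)), "shapes differ")
  expect_error(bceLoss(c(0.5, 0.5), c(1, 2)), "\\{0, 1\\}")
  expect_error(metrics(matrix(0.5, 2, 2), matrix(0, 3, 3)), "shapes differ")
  expect_error(metrics(matrix(0.5, 2, 2), matrix(0, 2, 2), threshold = 1.5),
               "threshold")
})
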