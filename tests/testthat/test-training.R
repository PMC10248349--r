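# Small-scale training/pipeline behaviour; network sizes are deliberately
# tiny so the whole file runs in well under a minute.

tinyData <- function(n = 8L, size = 32L, seed = 5L) {
  generateDataset(syntheticSpec(nSamples = n, imageSize = size, seed = seed))
}

tinyConfig <- function(epochs = 2L, seed = 1L, learningRate = 1e-3, ...) {
  trainConfig(network = wranetConfig(baseChannels = 2L, wavelet = "haar"),
              learningRate = learningRate, epochs = epochs, valFraction = 0.25,
              seed = seed, ...)
}

test_that("training is bitwise reproducible under a fixed seed", {
  ds <- tinyData()
  f1 <- trainModel(tinyConfig(), ds)
  f2 <- trainModel(tinyConfig(), ds)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$model@params, f2$model@params)
  f3 <- trainModel(tinyConfig(seed = 2L), ds)
  expect_false(identical(f1$log$trainLoss, f3$log$trainLoss))
})

test_that("optimization reduces the training loss on learnable data", {
  ds <- tinyData(n = 12L)
  fit <- trainModel(tinyConfig(epochs = 4L), ds)
  expect_lt(fit$log$trainLoss[4], fit$log$trainLoss[1])
})

test_that("non-finite losses abort with a diagnostic", {
  ds <- tinyData(n = 8L)
  cfg <- tinyConfig(epochs = 2L, learningRate = Inf)  # provoke divergence
  expect_error(trainModel(cfg, ds), "non-finite loss")
})

test_that("checkpoints round-trip through disk", {
  ds <- tinyData()
  fit <- trainModel(tinyConfig(), ds)
  path <- file.path(withr::local_tempdir(), "model.rds")
  saveCheckpoint(fit$model, path)
  expect_true(file.exists(sub("rds$", "json", path)))
  back <- loadCheckpoint(path)
  expect_equal(back@config@baseChannels, 2L)
  x <- ds[[1]]@image
  expect_identical(wranetForward(back, x), wranetForward(fit$model, x))
  # reloaded model reproduces the logged validation Dice
  vd <- wranet:::.evalDice(back@params, back@state, ds, fit$valIndex,
                           back@config)
  expect_equal(vd, fit$log$valDice[fit$bestEpoch])
})

test_that("cross-validation partitions the samples exactly once", {
  ds <- tinyData(n = 10L)
  cfg <- tinyConfig(epochs = 1L)
  cfg@cvFolds <- 5L
  cv <- crossValidate(cfg, ds)
  expect_length(cv$folds, 10L)
  expect_equal(as.integer(table(cv$folds)), rep(2L, 5L))   # 2 per fold
  expect_setequal(unlist(lapply(1:5, function(f) which(cv$folds == f))), 1:10)
  # same seed, same folds
  cv2 <- crossValidate(cfg, ds)
  expect_identical(cv$folds, cv2$folds)
  # summary mean equals the arithmetic mean of per-fold values
  expect_equal(cv$summary$mean[cv$summary$metric == "dice"],
               mean(vapply(cv$perFold, function(r) r@dice, numeric(1))))
  expect_error({ cfg@cvFolds <- 11L; crossValidate(cfg, ds) }, "exceeds")
})

test_that("prediction writes deterministic masks and resizes odd sizes back", {
  ds <- tinyData(n = 6L)
  fit <- trainModel(tinyConfig(epochs = 1L), ds)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- predictMasks(fit$model, list(ds[[1]]@image), outDir = d1, writeProb = TRUE)
  r2 <- predictMasks(fit$model, list(ds[[1]]@image), outDir = d2, writeProb = TRUE)
  f1 <- file.path(d1, "mask_0001.png"); f2 <- file.path(d2, "mask_0001.png")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_true(all(r1[[1]]$mask %in% c(0, 1)))
  # non-multiple-of-16 input: warn, resize, and return the original size
  odd <- ds[[2]]@image[1:30, 1:30, , drop = FALSE]
  expect_warning(ro <- predictMasks(fit$model, list(odd)), "resized")
  expect_equal(dim(ro[[1]]$prob), c(30L, 30L))
})

test_that("the CLI generates, trains, evaluates and decomposes end to end", {
  dataDir <- withr::local_tempdir()
  runDir <- withr::local_tempdir()
  wranetCLI(c("make-data", "--out", dataDir, "--n", "8", "--size", "32",
              "--seed", "3"))
  expect_true(file.exists(file.path(dataDir, "run.json")))
  expect_length(list.files(file.path(dataDir, "images")), 8L)
  suppressMessages(wranetCLI(c(
    "train", "--data", dataDir, "--out", runDir, "--epochs", "1",
    "--base-channels", "2", "--downsample", "wavelet:haar",
    "--lr", "0.001", "--seed", "1")))
  expect_true(file.exists(file.path(runDir, "model.rds")))
  rec <- jsonlite::read_json(file.path(runDir, "run.json"))
  expect_equal(rec$command, "train")
  log <- utils::read.csv(file.path(runDir, "training_log.csv"))
  expect_equal(nrow(log), 1L)
  evalDir <- withr::local_tempdir()
  suppressMessages(wranetCLI(c(
    "eval", "--data", dataDir, "--checkpoint",
    file.path(runDir, "model.rds"), "--out", evalDir)))
  mj <- jsonlite::read_json(file.path(evalDir, "metrics.json"))
  expect_true(all(c("dice", "iou", "precision", "sensitivity") %in% names(mj)))
  # demo decomposition grid
  grid <- file.path(runDir, "dwt.png")
  img <- file.path(dataDir, "images", "sample_0001.tif")
  wranetCLI(c("demo-dwt", "--image", img, "--wavelet", "haar", "--out", grid))
  expect_true(file.exists(grid))
  g <- png::readPNG(grid)
  expect_equal(dim(g), c(32L, 32L))
  # ablation flags parse into the expected configuration
  cfg <- wranet:::.cliNetwork(list("downsample" = "maxpool", "no-ram" = TRUE))
  expect_equal(cfg@downsample, "maxpool")
  expect_false(cfg@useRAM)
})

test_that("the demo grid reflects the subband layout", {
  img <- matrix(runif(16 * 16), 16, 16)
  out <- file.path(withr::local_tempdir(), "grid.png")
  s <- demoDecompose(img, "haar", out)
  expect_s4_class(s, "SubbandSet")
  # constant image: LL flat, detail panels exactly zero before scaling
  s2 <- demoDecompose(matrix(1, 8, 8), "haar",
                      file.path(withr::local_tempdir(), "c.png"))
  expect_equal(max(abs(lhBand(s2))), 0)
  # checkerboard: diagonal band carries the dominant energy
  cb <- outer(1:16, 1:16, function(i, j) (-1)^(i + j))
  s3 <- demoDecompose(cb, "haar", file.path(withr::local_tempdir(), "cb.png"))
  expect_gt(sum(hhBand(s3)^2),
            sum(llBand(s3)^2) + sum(lhBand(s3)^2) + sum(hlBand(s3)^2))
})
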