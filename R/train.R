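#' Create a training configuration
#'
#' Defaults follow the reference recipe: Adam (`beta1 = 0.9`,
#' `beta2 = 0.999`, `eps = 1e-8`, weight decay `5e-4`), learning rate
#' `1e-4`, batch size 4, 200 epochs, constant learning-rate schedule,
#' fivefold cross-validation. Scale `epochs`/`network` down for CPU-size
#' experiments.
#'
#' @param network a [WRANetConfig-class].
#' @param learningRate,beta1,beta2,eps,weightDecay Adam hyperparameters.
#' @param batchSize,epochs schedule.
#' @param valFraction held-out fraction for per-epoch validation (default
#'   0.2; 0 disables validation tracking).
#' @param cvFolds folds for [crossValidate()].
#' @param loss a [LossConfig-class].
#' @param lossKind `"hybrid"`, `"bce"` or `"dice"` (ablation switch).
#' @param seed controls initialization, shuffling, splits and folds.
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(network = wranetConfig(),
                        learningRate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, weightDecay = 5e-4,
                        batchSize = 4L, epochs = 200L,
                        valFraction = 0.2, cvFolds = 5L,
                        loss = lossConfig(), lossKind = "hybrid",
                        seed = 1L) {
  obj <- new("TrainConfig",
             learningRate = learningRate, beta1 = beta1, beta2 = beta2,
             eps = eps, weightDecay = weightDecay,
             batchSize = as.integer(batchSize), epochs = as.integer(epochs),
             valFraction = valFraction, cvFolds = as.integer(cvFolds),
             loss = loss, lossKind = lossKind,
             network = network, seed = as.integer(seed))
  validObject(obj)
  obj
}

.resolveSamples <- function(data) {
  if (is.character(data)) data <- readDataset(data)
  if (!length(data)) stop("empty dataset")
  for (s in data)
    if (!is(s, "SegmentationSample")) stop("dataset must contain SegmentationSample objects")
  d <- dim(data[[1]]@image)
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L)
    stop(sprintf("image size %d x %d is not divisible by 16", d[1], d[2]))
  data
}

.stackBatch <- function(samples, idx) {
  d <- dim(samples[[idx[1]]]@image)
  x <- array(0, c(d[1], d[2], d[3], length(idx)))
  y <- array(0, c(d[1], d[2], 1L, length(idx)))
  for (j in seq_along(idx)) {
    x[, , , j] <- samples[[idx[j]]]@image
    y[, , 1L, j] <- samples[[idx[j]]]@mask
  }
  list(x = x, y = y)
}

.adamUpdate <- function(P, G, opt, cfg) {
  opt$t <- opt$t + 1L
  b1 <- cfg@beta1; b2 <- cfg@beta2
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  for (nm in names(P)) {
    g <- G[[nm]] + cfg@weightDecay * P[[nm]]
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
    P[[nm]] <- P[[nm]] - cfg@learningRate * (opt$m[[nm]] / corr1) /
      (sqrt(opt$v[[nm]] / corr2) + cfg@eps)
  }
  list(P = P, opt = opt)
}

.evalDice <- function(P, S, samples, idx, config, batchSize = 8L) {
  if (!length(idx)) return(NA_real_)
  preds <- list(); gts <- list()
  for (chunk in split(idx, ceiling(seq_along(idx) / batchSize))) {
    b <- .stackBatch(samples, chunk)
    p <- .netForward(P, S, b$x, config, training = FALSE)$p
    for (j in seq_along(chunk)) {
      preds[[length(preds) + 1L]] <- matrix(p[, , 1L, j], dim(p)[1], dim(p)[2])
      gts[[length(gts) + 1L]] <- samples[[chunk[j]]]@mask
    }
  }
  metrics(preds, gts)@dice
}

#' Train a model
#'
#' Seeded mini-batch optimization of the configured loss with Adam.
#' Tracks per-epoch mean training loss and (when a validation split exists)
#' validation Dice; the returned model carries the parameters of the best
#' validation epoch (or the final epoch when `valFraction = 0`). Fully
#' reproducible: same config, data and seed give identical results under
#' single-threaded execution.
#'
#' @param config a [TrainConfig-class].
#' @param data a list of [SegmentationSample-class] or a dataset directory
#'   (see [writeDataset()]).
#' @param verbose print per-epoch progress.
#' @return object of class `"wranetTraining"`: list with `model`
#'   ([WRANetModel-class]), `log` (data.frame epoch/trainLoss/valDice),
#'   `bestEpoch`, `valIndex`, `config`.
#' @export
trainModel <- function(config, data, verbose = FALSE) {
  stopifnot(is(config, "TrainConfig"))
  samples <- .resolveSamples(data)
  set.seed(config@seed)
  nVal <- floor(config@valFraction * length(samples))
  perm <- sample(length(samples))
  valIdx <- if (nVal > 0) perm[seq_len(nVal)] else integer(0)
  trIdx <- setdiff(perm, valIdx)
  if (!length(trIdx)) stop("no training samples left after validation split")
  model <- wranetInit(config@network, seed = config@seed)
  P <- model@params; S <- model@state
  zeros <- lapply(P, function(p) p * 0)
  opt <- list(m = zeros, v = zeros, t = 0L)
  log <- data.frame(epoch = integer(), trainLoss = numeric(), valDice = numeric())
  best <- list(dice = -Inf, P = P, S = S, epoch = 0L)
  for (ep in seq_len(config@epochs)) {
    ord <- sample(trIdx)
    batches <- split(ord, ceiling(seq_along(ord) / config@batchSize))
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      b <- .stackBatch(samples, batches[[bi]])
      fw <- .netForward(P, S, b$x, config@network, training = TRUE, withCache = TRUE)
      S <- fw$S
      lg <- .lossWithGrad(fw$p, b$y, config@loss, config@lossKind)
      if (!is.finite(lg$loss))
        stop(sprintf("non-finite loss at epoch %d batch %d; reduce the learning rate",
                     ep, bi))
      losses[bi] <- lg$loss
      dp <- array(lg$grad, dim(fw$p))
      G <- .netBackward(P, config@network, fw$caches, dp)
      up <- .adamUpdate(P, G, opt, config)
      P <- up$P; opt <- up$opt
    }
    vd <- .evalDice(P, S, samples, valIdx, config@network)
    log <- rbind(log, data.frame(epoch = ep, trainLoss = mean(losses), valDice = vd))
    if (verbose)
      message(sprintf("epoch %3d  train loss %.4f  val Dice %s",
                      ep, mean(losses),
                      if (is.na(vd)) "-" else sprintf("%.4f", vd)))
    if (!is.na(vd) && vd > best$dice)
      best <- list(dice = vd, P = P, S = S, epoch = ep)
  }
  if (!length(valIdx)) best <- list(dice = NA_real_, P = P, S = S, epoch = config@epochs)
  model@params <- best$P
  model@state <- best$S
  structure(list(model = model, log = log, bestEpoch = best$epoch,
                 valIndex = sort(valIdx), config = config),
            class = "wranetTraining")
}

#' @export
print.wranetTraining <- function(x, ...) {
  cat(sprintf("wranetTraining: %d epochs, best validation Dice %s (epoch %d)\n",
              nrow(x$log),
              if (all(is.na(x$log$valDice))) "-" else
                sprintf("%.4f", max(x$log$valDice, na.rm = TRUE)),
              x$bestEpoch))
  invisible(x)
}

#' Seeded k-fold cross-validation
#'
#' Partitions the samples into `cvFolds` disjoint folds covering every
#' sample exactly once, trains on the complement of each fold and evaluates
#' on the fold. Per-fold metrics and their mean and standard deviation are
#' returned.
#'
#' @inheritParams trainModel
#' @return list with `perFold` (list of [MetricsReport-class]), `summary`
#'   (data.frame of mean and sd per metric), `folds` (fold assignment
#'   integer vector), `models` (per-fold [WRANetModel-class]).
#' @export
crossValidate <- function(config, data, verbose = FALSE) {
  stopifnot(is(config, "TrainConfig"))
  samples <- .resolveSamples(data)
  k <- config@cvFolds
  if (k > length(samples))
    stop(sprintf("cvFolds (%d) exceeds the number of samples (%d)", k, length(samples)))
  set.seed(config@seed)
  folds <- sample(rep(seq_len(k), length.out = length(samples)))
  perFold <- vector("list", k)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    testIdx <- which(folds == f)
    trainSamples <- samples[folds != f]
    foldCfg <- config
    foldCfg@valFraction <- 0
    fit <- trainModel(foldCfg, trainSamples, verbose = FALSE)
    models[[f]] <- fit$model
    preds <- lapply(testIdx, function(i)
      wranetForward(fit$model, samples[[i]]@image)[, , 1L])
    gts <- lapply(testIdx, function(i) samples[[i]]@mask)
    perFold[[f]] <- metrics(preds, gts)
    if (verbose)
      message(sprintf("fold %d/%d: Dice %.4f", f, k, perFold[[f]]@dice))
  }
  vals <- sapply(perFold, function(r)
    c(dice = r@dice, iou = r@iou, precision = r@precision,
      sensitivity = r@sensitivity))
  summary <- data.frame(metric = rownames(vals),
                        mean = rowMeans(vals),
                        sd = apply(vals, 1, sd))
  list(perFold = perFold, summary = summary, folds = folds, models = models)
}

#' Save / load model checkpoints
#'
#' A checkpoint is a serialized parameter archive (`.rds`) plus a JSON
#' sidecar (`.json`) recording the network configuration (wavelet included)
#' and the package version.
#'
#' @param model a [WRANetModel-class].
#' @param path checkpoint path (`.rds` appended if missing).
#' @return `saveCheckpoint`: the path, invisibly. `loadCheckpoint`: the
#'   restored [WRANetModel-class].
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "WRANetModel"))
  if (!grepl("\\.rds$", path)) path <- paste0(path, ".rds")
  saveRDS(list(params = model@params, state = model@state), path)
  cfg <- model@config
  side <- list(
    network = list(inChannels = cfg@inChannels, baseChannels = cfg@baseChannels,
                   depth = cfg@depth, wavelet = waveletName(cfg@wavelet),
                   downsample = cfg@downsample, useRAM = cfg@useRAM),
    package_version = as.character(utils::packageVersion("wranet")))
  jsonlite::write_json(side, sub("\\.rds$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!grepl("\\.rds$", path)) path <- paste0(path, ".rds")
  blob <- readRDS(path)
  side <- jsonlite::read_json(sub("\\.rds$", ".json", path))
  nw <- side$network
  config <- wranetConfig(inChannels = nw$inChannels,
                         baseChannels = nw$baseChannels,
                         wavelet = nw$wavelet,
                         downsample = nw$downsample,
                         useRAM = isTRUE(nw$useRAM))
  new("WRANetModel", config = config, params = blob$params, state = blob$state)
}

#' Predict segmentation masks
#'
#' Runs the model on images (arrays or image file paths), binarizes at
#' `threshold`, and optionally writes PNG masks (plus probability maps).
#' Images whose side is not divisible by 16 are bilinearly resized up to
#' the next multiple (with a warning) and the mask is resized back.
#'
#' @param model a [WRANetModel-class] or a checkpoint path.
#' @param images list of `H x W (x C)` arrays or character file paths.
#' @param threshold binarization threshold.
#' @param outDir optional output directory for `mask_*.png` (and
#'   `prob_*.png` when `writeProb = TRUE`).
#' @param writeProb also write probability maps.
#' @return invisibly, a list with per-image `prob` and `mask` arrays.
#' @export
predictMasks <- function(model, images, threshold = 0.5, outDir = NULL,
                         writeProb = FALSE) {
  if (is.character(model)) model <- loadCheckpoint(model)
  stopifnot(is(model, "WRANetModel"))
  if (!is.list(images)) images <- as.list(images)
  if (!is.null(outDir) && !dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  out <- lapply(seq_along(images), function(i) {
    im <- images[[i]]
    if (is.character(im)) im <- .readImageFile(im)
    if (length(dim(im)) == 2L) im <- array(im, c(dim(im), 1L))
    d0 <- dim(im)
    hw <- c(d0[1], d0[2])
    target <- 16L * ceiling(hw / 16L)
    if (any(target != hw)) {
      warning(sprintf("image %d resized from %d x %d to %d x %d (must be divisible by 16)",
                      i, hw[1], hw[2], target[1], target[2]))
      im <- .resizeBilinear(im, target[1], target[2])
    }
    if (dim(im)[3] != model@config@inChannels) {
      if (model@config@inChannels == 1L)
        im <- array(rowMeans(matrix(im, prod(dim(im)[1:2]), dim(im)[3])),
                    c(dim(im)[1:2], 1L))
      else stop(sprintf("image %d has %d channels; model expects %d",
                        i, dim(im)[3], model@config@inChannels))
    }
    p <- wranetForward(model, im)[, , 1L]
    if (any(target != hw))
      p <- .resizeBilinear(array(p, c(dim(p), 1L)), hw[1], hw[2])[, , 1L]
    mask <- (p >= threshold) * 1
    if (!is.null(outDir)) {
      png::writePNG(mask, file.path(outDir, sprintf("mask_%04d.png", i)))
      if (writeProb)
        png::writePNG(pmin(pmax(p, 0), 1),
                      file.path(outDir, sprintf("prob_%04d.png", i)))
    }
    list(prob = p, mask = mask)
  })
  invisible(out)
}
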