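#' Wavelet specification
#'
#' Identifies one wavelet family/order combination. Orthogonal families
#' (`haar`, `db`, `sym`) take an integer scale `S` with `1 <= S <= 7`
#' (filter length `2S`; `haar` forces `S = 1`). Biorthogonal families
#' (`bior`, `rbio`) take a two-digit order printed as e.g. `"2.2"`, drawn
#' from `{1.1, 2.2, 3.3, 4.4}`.
#'
#' @slot family character, one of `"haar"`, `"db"`, `"sym"`, `"bior"`, `"rbio"`.
#' @slot order character, the order as printed in the wavelet name
#'   (`"1"`..`"7"` or `"1.1"`, `"2.2"`, `"3.3"`, `"4.4"`).
#' @exportClass WaveletSpec
setClass("WaveletSpec",
  representation(family = "character", order = "character"))

setValidity("WaveletSpec", function(object) {
  fam <- object@family
  ord <- object@order
  if (length(fam) != 1L || length(ord) != 1L)
    return("family and order must be length-1 character")
  if (!fam %in% c("haar", "db", "sym", "bior", "rbio"))
    return(sprintf("unsupported wavelet family '%s'; valid: haar, db, sym, bior, rbio", fam))
  if (fam %in% c("haar", "db", "sym")) {
    s <- suppressWarnings(as.integer(ord))
    if (is.na(s) || s < 1L || s > 7L)
      return(sprintf("orthogonal order '%s' invalid; scale S must satisfy 1 <= S <= 7", ord))
    if (fam == "haar" && s != 1L)
      return("family haar forces S = 1")
  } else {
    if (!ord %in% c("1.1", "2.2", "3.3", "4.4"))
      return(sprintf("biorthogonal order '%s' invalid; valid orders: 1.1, 2.2, 3.3, 4.4", ord))
  }
  TRUE
})

#' Quadrature-mirror wavelet filter bank
#'
#' Analysis and synthesis low/high-pass filter coefficient vectors for one
#' wavelet. The analysis pair `(l, h)` decomposes a signal; the synthesis
#' pair reconstructs it. High-pass filters are always derived from the
#' low-pass filters by the alternating-sign index-reversal recurrence
#' `h_i = (-1)^i lt_{2n+1-i}` (orthogonal banks are self-dual, `lt = l`).
#'
#' @slot analysisLow numeric, the analysis low-pass filter `l`.
#' @slot analysisHigh numeric, the analysis high-pass filter `h`.
#' @slot synthesisLow numeric, the synthesis low-pass filter (`l` with a
#'   tilde in the usual notation; equals `analysisLow` for orthogonal banks).
#' @slot synthesisHigh numeric, the synthesis high-pass filter.
#' @slot spec the [WaveletSpec-class] the bank was built from.
#' @seealso [buildFilterBank()], [validateBank()]
#' @exportClass WaveletFilterBank
setClass("WaveletFilterBank",
  representation(
    analysisLow   = "numeric",
    analysisHigh  = "numeric",
    synthesisLow  = "numeric",
    synthesisHigh = "numeric",
    spec          = "WaveletSpec"))

setValidity("WaveletFilterBank", function(object) {
  n <- length(object@analysisLow)
  if (n < 2L || n %% 2L != 0L)
    return("filter length must be even and >= 2")
  lens <- c(length(object@analysisHigh), length(object@synthesisLow),
            length(object@synthesisHigh))
  if (!all(lens == n))
    return("all four filters must share one length")
  if (!all(is.finite(c(object@analysisLow, object@analysisHigh,
                       object@synthesisLow, object@synthesisHigh))))
    return("filter coefficients must be finite")
  TRUE
})

#' One-level 2D-DWT subband set
#'
#' The four outputs of one separable 2D discrete wavelet transform level of
#' a `H x W x C` feature map: the approximation `LL` and the three detail
#' orientations. Naming follows the row-first convention: `LH` is row
#' (horizontal) high-pass then column low-pass, `HL` is row low-pass then
#' column high-pass, `HH` is diagonal. All four subbands have shape
#' `H/2 x W/2 x C`.
#'
#' @slot ll,lh,hl,hh numeric arrays of identical shape `H/2 x W/2 x C`.
#' @seealso [dwt2()], [idwt2()]
#' @exportClass SubbandSet
setClass("SubbandSet",
  representation(ll = "array", lh = "array", hl = "array", hh = "array"))

setValidity("SubbandSet", function(object) {
  d <- dim(object@ll)
  for (nm in c("lh", "hl", "hh"))
    if (!identical(dim(slot(object, nm)), d))
      return("all four subbands must share one shape")
  TRUE
})

#' Network configuration
#'
#' Describes one network instance: a 4-level encoder/decoder whose channel
#' ladder doubles per level, `baseChannels, 2x, 4x, 8x` with a `16x`
#' bottleneck (the reference configuration is `baseChannels = 64`, giving
#' 64/128/256/512/1024). Input height and width must be divisible by
#' `2^depth`.
#'
#' @slot inChannels integer, 1 (grayscale) or 3 (RGB).
#' @slot baseChannels integer, channels of the first encoder level.
#' @slot depth integer, number of down/upsampling levels (4).
#' @slot wavelet the [WaveletSpec-class] used by every downsampling stage.
#' @slot downsample `"wavelet"` (LL-only DWT) or `"maxpool"` (2x2 ablation).
#' @slot useRAM logical; `FALSE` bypasses the attention gates (skip features
#'   are concatenated ungated), an ablation switch.
#' @exportClass WRANetConfig
setClass("WRANetConfig",
  representation(
    inChannels   = "integer",
    baseChannels = "integer",
    depth        = "integer",
    wavelet      = "WaveletSpec",
    downsample   = "character",
    useRAM       = "logical"))

setValidity("WRANetConfig", function(object) {
  if (!object@inChannels %in% c(1L, 3L))
    return("inChannels must be 1 or 3")
  if (object@baseChannels < 1L)
    return("baseChannels must be >= 1")
  if (object@depth != 4L)
    return("depth must be 4")
  if (!object@downsample %in% c("wavelet", "maxpool"))
    return("downsample must be 'wavelet' or 'maxpool'")
  TRUE
})

#' A wavelet residual attention segmentation model
#'
#' Holds the configuration, all trainable parameters (a flat named list of
#' arrays) and non-trainable state (batch-normalization running statistics).
#' Construct with [wranetInit()]; run with [wranetForward()]; train with
#' [trainModel()].
#'
#' @slot config a [WRANetConfig-class].
#' @slot params named list of numeric arrays, the trainable parameters.
#' @slot state named list, running means/variances and bookkeeping.
#' @exportClass WRANetModel
setClass("WRANetModel",
  representation(config = "WRANetConfig", params = "list", state = "list"))

#' Hybrid loss configuration
#'
#' Weights and numerical guards for the mixed binary cross-entropy + Dice
#' segmentation loss `L = alpha * L_BCE + beta * L_Dice`.
#'
#' @slot alphaWeight numeric in `[0, 1]`, BCE weight (default 0.4).
#' @slot betaWeight numeric in `[0, 1]`, Dice weight (default 0.6).
#' @slot lambdaSmooth positive numeric, Dice smoothing factor (default 1).
#' @slot clampEps small positive numeric; probabilities are clamped to
#'   `[eps, 1 - eps]` before logarithms (default 1e-7).
#' @exportClass LossConfig
setClass("LossConfig",
  representation(
    alphaWeight  = "numeric",
    betaWeight   = "numeric",
    lambdaSmooth = "numeric",
    clampEps     = "numeric"))

setValidity("LossConfig", function(object) {
  if (object@alphaWeight < 0 || object@alphaWeight > 1)
    return("alphaWeight must lie in [0, 1]")
  if (object@betaWeight < 0 || object@betaWeight > 1)
    return("betaWeight must lie in [0, 1]")
  if (object@lambdaSmooth <= 0)
    return("lambdaSmooth must be positive")
  if (object@clampEps <= 0 || object@clampEps >= 0.5)
    return("clampEps must lie in (0, 0.5)")
  TRUE
})

#' Segmentation evaluation report
#'
#' Dice, IoU, precision and sensitivity together with the confusion counts
#' they derive from. Metric slots hold fractions in `[0, 1]`.
#'
#' @slot dice,iou,precision,sensitivity numeric in `[0, 1]`.
#' @slot tp,fp,fn,tn numeric, summed confusion counts over the set.
#' @slot nImages integer, number of images aggregated.
#' @slot aggregate `"macro"` (per-image metrics averaged) or `"micro"`
#'   (metrics from pooled counts).
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(
    dice = "numeric", iou = "numeric",
    precision = "numeric", sensitivity = "numeric",
    tp = "numeric", fp = "numeric", fn = "numeric", tn = "numeric",
    nImages = "integer", aggregate = "character"))

#' Synthetic lesion dataset specification
#'
#' Parameters of the pseudo-tumor image generator: dark textured background,
#' one or more bright irregular blobs (randomly deformed ellipses with a
#' Gaussian intensity profile) whose filled footprint is the ground-truth
#' mask, plus configurable additive noise. Diameter presets emulate clinical
#' size strata at a documented 2 px/mm scale: `"large"` (> 7 mm -> > 14 px),
#' `"medium"` (3-7 mm -> 6-14 px), `"small"` (< 3 mm -> < 6 px).
#'
#' @slot nSamples integer, number of image/mask pairs.
#' @slot imageSize integer side length, a multiple of 16.
#' @slot channels integer, 1 or 3.
#' @slot lesionDiameterRange numeric length-2, min/max lesion diameter (px).
#' @slot lesionsPerImage integer length-2, min/max blob count per image.
#' @slot textureAmplitude numeric, amplitude of the smooth background texture.
#' @slot noiseModel character: `"none"`, `"gaussian"`, `"checkerboard"`,
#'   or `"saltpepper"`.
#' @slot noiseMagnitude numeric: the sd, amplitude, or corruption rate of the
#'   noise model.
#' @slot seed integer RNG seed; the dataset is a pure function of the spec.
#' @slot allowEmpty logical, permit images without lesions.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(
    nSamples = "integer", imageSize = "integer", channels = "integer",
    lesionDiameterRange = "numeric", lesionsPerImage = "integer",
    textureAmplitude = "numeric", noiseModel = "character",
    noiseMagnitude = "numeric", seed = "integer", allowEmpty = "logical"))

setValidity("SyntheticSpec", function(object) {
  msgs <- character()
  if (object@nSamples < 1L) msgs <- c(msgs, "nSamples must be >= 1")
  if (object@imageSize %% 16L != 0L || object@imageSize < 16L)
    msgs <- c(msgs, "imageSize must be a positive multiple of 16")
  if (!object@channels %in% c(1L, 3L)) msgs <- c(msgs, "channels must be 1 or 3")
  dr <- object@lesionDiameterRange
  if (length(dr) != 2L || any(dr <= 0) || dr[1] > dr[2])
    msgs <- c(msgs, "lesionDiameterRange must be positive and ordered")
  else if (dr[2] >= object@imageSize / 2)
    msgs <- c(msgs, "lesionDiameterRange must stay below imageSize/2")
  lp <- object@lesionsPerImage
  if (length(lp) != 2L || any(lp < 0L) || lp[1] > lp[2])
    msgs <- c(msgs, "lesionsPerImage must be a non-negative ordered range")
  if (object@textureAmplitude < 0) msgs <- c(msgs, "textureAmplitude must be >= 0")
  if (!object@noiseModel %in% c("none", "gaussian", "checkerboard", "saltpepper"))
    msgs <- c(msgs, "noiseModel must be one of none, gaussian, checkerboard, saltpepper")
  if (object@noiseMagnitude < 0) msgs <- c(msgs, "noiseMagnitude must be >= 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' An image paired with its binary ground-truth mask
#'
#' @slot image numeric array `H x W x C` with values in `[0, 1]`.
#' @slot mask integer/numeric matrix `H x W` with values in `{0, 1}`.
#' @slot metadata list: lesion count, diameters, per-sample seed.
#' @exportClass SegmentationSample
setClass("SegmentationSample",
  representation(image = "array", mask = "matrix", metadata = "list"))

setValidity("SegmentationSample", function(object) {
  if (!all(object@mask %in% c(0, 1)))
    return("mask must be binary")
  if (mean(object@mask) >= 0.5)
    return("mask foreground fraction must stay below 0.5")
  d <- dim(object@image)
  if (length(d) != 3L || d[1] != nrow(object@mask) || d[2] != ncol(object@mask))
    return("image must be H x W x C matching the mask")
  if (!all(is.finite(object@image)))
    return("image must be finite")
  TRUE
})

#' Training configuration
#'
#' Optimizer and schedule settings. Defaults follow the reference training
#' recipe: Adam with `beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`, weight
#' decay `5e-4`, learning rate `1e-4`, batch size 4, 200 epochs (scale
#' `epochs` down for desk-size experiments).
#'
#' @slot learningRate,beta1,beta2,eps,weightDecay numeric Adam settings.
#' @slot batchSize,epochs integer schedule.
#' @slot valFraction numeric in `[0, 1)`, held-out fraction used for
#'   per-epoch validation Dice when training on a flat sample list.
#' @slot cvFolds integer, folds for [crossValidate()] (>= 2).
#' @slot loss a [LossConfig-class]; `lossKind` may restrict it to a pure
#'   `"bce"` or `"dice"` objective for ablations (default `"hybrid"`).
#' @slot lossKind character.
#' @slot network a [WRANetConfig-class].
#' @slot seed integer, controls init, shuffling and fold assignment.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(
    learningRate = "numeric", beta1 = "numeric", beta2 = "numeric",
    eps = "numeric", weightDecay = "numeric",
    batchSize = "integer", epochs = "integer",
    valFraction = "numeric", cvFolds = "integer",
    loss = "LossConfig", lossKind = "character",
    network = "WRANetConfig", seed = "integer"))

setValidity("TrainConfig", function(object) {
  if (object@learningRate <= 0) return("learningRate must be positive")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@valFraction < 0 || object@valFraction >= 1)
    return("valFraction must lie in [0, 1)")
  if (object@cvFolds < 2L) return("cvFolds must be >= 2")
  if (!object@lossKind %in% c("hybrid", "bce", "dice"))
    return("lossKind must be hybrid, bce or dice")
  TRUE
})
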