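# Reproducible pseudo-tumor dataset generator: smooth textured dark
# background, one or more bright irregular blobs (deformed ellipses with a
# Gaussian intensity profile) whose filled footprint defines the mask, plus
# configurable additive high-frequency noise.

#' Diameter presets for clinical size strata
#'
#' Maps lesion-size strata to pixel diameter ranges at a fixed documented
#' scale of 2 px/mm (so a 64 x 64 image stands for a ~32 mm field of view):
#' `"large"` > 7 mm -> (14, 24) px, `"medium"` 3--7 mm -> (6, 14) px,
#' `"small"` < 3 mm -> (2, 6) px.
#'
#' @param preset one of `"large"`, `"medium"`, `"small"`.
#' @return numeric length-2 diameter range in pixels.
#' @export
diameterPreset <- function(preset = c("medium", "large", "small")) {
  switch(match.arg(preset),
         large = c(14, 24), medium = c(6, 14), small = c(2, 6))
}

#' Create a synthetic dataset specification
#'
#' @param nSamples number of image/mask pairs.
#' @param imageSize side length, a multiple of 16.
#' @param channels 1 (grayscale) or 3 (RGB).
#' @param lesionDiameterRange length-2 pixel diameter range, or a preset
#'   name understood by [diameterPreset()].
#' @param lesionsPerImage length-2 integer range of blobs per image.
#' @param textureAmplitude amplitude of the smooth background texture
#'   (sum of low-frequency sinusoids) on the `[0, 1]` intensity scale.
#' @param noiseModel `"none"`, `"gaussian"`, `"checkerboard"`, `"saltpepper"`.
#' @param noiseMagnitude sd / amplitude / corruption rate of the noise.
#' @param seed integer; the dataset is a pure function of the spec.
#' @param allowEmpty permit images with zero lesions (otherwise at least one
#'   lesion is guaranteed).
#' @return a validated [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nSamples = 100L, imageSize = 64L, channels = 1L,
                          lesionDiameterRange = "medium",
                          lesionsPerImage = c(1L, 3L),
                          textureAmplitude = 0.15,
                          noiseModel = "gaussian", noiseMagnitude = 0.05,
                          seed = 1L, allowEmpty = FALSE) {
  if (is.character(lesionDiameterRange))
    lesionDiameterRange <- diameterPreset(lesionDiameterRange)
  if (length(lesionsPerImage) == 1L) lesionsPerImage <- rep(lesionsPerImage, 2L)
  obj <- new("SyntheticSpec",
             nSamples = as.integer(nSamples), imageSize = as.integer(imageSize),
             channels = as.integer(channels),
             lesionDiameterRange = as.numeric(lesionDiameterRange),
             lesionsPerImage = as.integer(lesionsPerImage),
             textureAmplitude = as.numeric(textureAmplitude),
             noiseModel = noiseModel, noiseMagnitude = as.numeric(noiseMagnitude),
             seed = as.integer(seed), allowEmpty = isTRUE(allowEmpty))
  validObject(obj)
  obj
}

# smooth background: base level plus a few low-frequency random sinusoids
.backgroundTexture <- function(n, amplitude) {
  xs <- matrix(seq_len(n), n, n)
  ys <- t(xs)
  tex <- matrix(0, n, n)
  for (k in 1:4) {
    fx <- runif(1, 0.5, 3); fy <- runif(1, 0.5, 3); ph <- runif(1, 0, 2 * pi)
    tex <- tex + sin(2 * pi * (fx * xs + fy * ys) / n + ph) / k
  }
  0.18 + amplitude * tex / max(abs(range(tex)), 1e-12)
}

# one deformed-ellipse lesion; returns its footprint and intensity layer
.drawLesion <- function(n, diamRange) {
  lo <- diamRange[1]; hi <- diamRange[2]
  pad <- 0.1 * (hi - lo)
  d <- runif(1, lo + pad, hi - pad)
  r0 <- d / 2
  margin <- ceiling(hi / 2) + 2
  cx <- runif(1, margin, n - margin)
  cy <- runif(1, margin, n - margin)
  rot <- runif(1, 0, pi)
  sx <- runif(1, 0.85, 1.15); sy <- 1 / sx      # area-preserving eccentricity
  ak <- runif(3, 0, 0.25) / (2:4)               # sinusoidal boundary modes 2..4
  ph <- runif(3, 0, 2 * pi)
  peak <- runif(1, 0.75, 0.9)
  xs <- matrix(seq_len(n), n, n) - cy           # rows = y
  ys <- t(matrix(seq_len(n), n, n)) - cx        # cols = x
  u <- (cos(rot) * ys + sin(rot) * xs) / sx
  v <- (-sin(rot) * ys + cos(rot) * xs) / sy
  rr <- sqrt(u^2 + v^2)
  th <- atan2(v, u)
  rb <- r0 * (1 + ak[1] * sin(2 * th + ph[1]) + ak[2] * sin(3 * th + ph[2]) +
                ak[3] * sin(4 * th + ph[3]))
  inside <- rr <= rb
  if (!any(inside)) inside[round(cy), round(cx)] <- TRUE
  intensity <- peak * exp(-0.5 * (rr / (0.7 * rb))^2)
  list(mask = inside, intensity = intensity * (rr <= 1.4 * rb),
       equivDiameter = 2 * sqrt(sum(inside) / pi))
}

#' Add noise to an image
#'
#' Pure additive/corruptive perturbation, seed-controlled; magnitude 0
#' returns the input unchanged. Models: `"gaussian"` adds i.i.d.
#' `N(0, magnitude^2)`; `"checkerboard"` adds the Nyquist pattern
#' `magnitude * (-1)^(i+j)` (annihilated exactly by the Haar low-pass
#' branch); `"saltpepper"` sets a `magnitude` fraction of pixels to 0 or 1;
#' `"none"` is the identity. No clamping is applied.
#'
#' @param image matrix or `H x W x C` array.
#' @param model noise model name.
#' @param magnitude non-negative scalar.
#' @param seed RNG seed.
#' @return perturbed image, same shape.
#' @export
addNoise <- function(image, model = c("gaussian", "checkerboard", "saltpepper", "none"),
                     magnitude, seed = 1L) {
  model <- match.arg(model)
  if (magnitude < 0) stop("magnitude must be >= 0")
  if (magnitude == 0 || model == "none") return(image)
  d <- if (is.null(dim(image))) stop("image must be a matrix or array") else dim(image)
  H <- d[1]; W <- d[2]
  set.seed(as.integer(seed))
  switch(model,
    gaussian = image + array(rnorm(length(image), 0, magnitude), d),
    checkerboard = {
      cb <- outer(seq_len(H), seq_len(W), function(i, j) (-1)^(i + j))
      image + magnitude * array(cb, d)
    },
    saltpepper = {
      out <- image
      idx <- which(runif(length(image)) < magnitude)
      out[idx] <- as.numeric(runif(length(idx)) < 0.5)
      out
    })
}

#' Generate a synthetic segmentation dataset
#'
#' Deterministic given the spec (identical spec, identical dataset): each
#' sample is a smooth textured dark background with bright deformed-ellipse
#' lesions whose union footprint is the binary mask, plus the configured
#' noise; intensities are clamped to `[0, 1]` at the end.
#'
#' @param spec a [SyntheticSpec-class] (see [syntheticSpec()]).
#' @return list of [SegmentationSample-class] objects.
#' @examples
#' ds <- generateDataset(syntheticSpec(nSamples = 2L, imageSize = 32L))
#' dim(ds[[1]]@image)
#' @export
generateDataset <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  set.seed(spec@seed)
  n <- spec@imageSize
  lapply(seq_len(spec@nSamples), function(i) {
    nles <- if (spec@lesionsPerImage[2] == spec@lesionsPerImage[1])
      spec@lesionsPerImage[1]
    else sample(spec@lesionsPerImage[1]:spec@lesionsPerImage[2], 1L)
    if (nles == 0L && !spec@allowEmpty) nles <- 1L
    img <- .backgroundTexture(n, spec@textureAmplitude)
    mask <- matrix(FALSE, n, n)
    diams <- numeric(0)
    if (nles > 0L) for (j in seq_len(nles)) {
      les <- .drawLesion(n, spec@lesionDiameterRange)
      mask <- mask | les$mask
      img <- pmax(img, les$intensity)
      diams <- c(diams, les$equivDiameter)
    }
    noiseSeed <- sample.int(.Machine$integer.max, 1L)
    if (spec@noiseModel != "none" && spec@noiseMagnitude > 0)
      img <- addNoise(img, spec@noiseModel, spec@noiseMagnitude, seed = noiseSeed)
    img <- pmin(pmax(img, 0), 1)
    arr <- if (spec@channels == 1L) array(img, c(n, n, 1L))
           else array(rep(img, 3L), c(n, n, 3L))
    new("SegmentationSample",
        image = arr,
        mask = matrix(as.numeric(mask), n, n),
        metadata = list(index = i, lesionCount = nles,
                        equivDiameters = diams, specSeed = spec@seed,
                        noiseSeed = noiseSeed))
  })
}
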