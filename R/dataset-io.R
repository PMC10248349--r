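# Dataset serialization: images/ and masks/ subdirectories plus
# manifest.json. Grayscale images are written as 16-bit TIFF (lossless to
# 1/65535), RGB images and all masks as 8-bit PNG (masks use {0, 255}).

.specToList <- function(spec) {
  list(nSamples = spec@nSamples, imageSize = spec@imageSize,
       channels = spec@channels,
       lesionDiameterRange = spec@lesionDiameterRange,
       lesionsPerImage = spec@lesionsPerImage,
       textureAmplitude = spec@textureAmplitude,
       noiseModel = spec@noiseModel, noiseMagnitude = spec@noiseMagnitude,
       seed = spec@seed, allowEmpty = spec@allowEmpty)
}

.specFromList <- function(x) {
  syntheticSpec(nSamples = x$nSamples, imageSize = x$imageSize,
                channels = x$channels,
                lesionDiameterRange = unlist(x$lesionDiameterRange),
                lesionsPerImage = unlist(x$lesionsPerImage),
                textureAmplitude = x$textureAmplitude,
                noiseModel = x$noiseModel, noiseMagnitude = x$noiseMagnitude,
                seed = x$seed, allowEmpty = isTRUE(x$allowEmpty))
}

#' Write a dataset to disk
#'
#' Writes paired image/mask files plus a JSON manifest recording filenames,
#' per-sample metadata and (when given) the generating spec. The layout is
#' `directory/images/`, `directory/masks/`, `directory/manifest.json`.
#' Round-trips losslessly through [readDataset()] (masks bitwise, grayscale
#' images to 16-bit quantization).
#'
#' @param samples list of [SegmentationSample-class] objects.
#' @param directory target directory (created if needed).
#' @param spec optional [SyntheticSpec-class] recorded in the manifest.
#' @return the manifest, invisibly.
#' @export
writeDataset <- function(samples, directory, spec = NULL) {
  for (sub in c("", "images", "masks")) {
    d <- file.path(directory, sub)
    if (!dir.exists(d) && !dir.create(d, recursive = TRUE))
      stop(sprintf("cannot create directory '%s'", d))
  }
  entries <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    stopifnot(is(s, "SegmentationSample"))
    gray <- dim(s@image)[3] == 1L
    imgFile <- sprintf("images/sample_%04d.%s", i, if (gray) "tif" else "png")
    maskFile <- sprintf("masks/sample_%04d.png", i)
    ok <- tryCatch({
      if (gray)
        tiff::writeTIFF(s@image[, , 1L], file.path(directory, imgFile),
                        bits.per.sample = 16L)
      else
        png::writePNG(s@image, file.path(directory, imgFile))
      png::writePNG(s@mask, file.path(directory, maskFile))
      TRUE
    }, error = function(e)
      stop(sprintf("failed writing sample %d under '%s': %s",
                   i, directory, conditionMessage(e))))
    c(list(image = imgFile, mask = maskFile), s@metadata)
  })
  manifest <- list(
    format = "wranet-dataset/1",
    package_version = as.character(utils::packageVersion("wranet")),
    n_samples = length(samples),
    spec = if (!is.null(spec)) .specToList(spec),
    samples = entries)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.readImageFile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    nii = , gz = .readNiftiSlice(path),
    stop(sprintf("unsupported image format '%s' for '%s'", ext, path)))
  if (is.null(dim(img)) || length(dim(img)) == 2L)
    img <- array(img, c(dim(as.matrix(img)), 1L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(img)[3] == 2L) img <- img[, , 1L, drop = FALSE]   # gray + alpha
  img
}

# optional NIfTI support: middle axial slice, rescaled to [0, 1]
.readNiftiSlice <- function(path, slice = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI requires the RNifti package")
  vol <- RNifti::asNifti(RNifti::readNifti(path))
  a <- as.array(vol)
  if (length(dim(a)) >= 3L) {
    if (is.null(slice)) slice <- ceiling(dim(a)[3] / 2)
    a <- a[, , slice]
  }
  rng <- range(a)
  if (diff(rng) > 0) a <- (a - rng[1]) / diff(rng)
  array(a, c(dim(a), 1L))
}

#' Read a dataset written by [writeDataset()]
#'
#' @param directory dataset directory containing `manifest.json`.
#' @return list of [SegmentationSample-class]; the generating spec (if
#'   recorded) is attached as attribute `"spec"`.
#' @export
readDataset <- function(directory) {
  mf <- file.path(directory, "manifest.json")
  if (!file.exists(mf))
    stop(sprintf("no manifest.json in '%s'", directory))
  manifest <- jsonlite::read_json(mf)
  samples <- lapply(manifest$samples, function(e) {
    img <- .readImageFile(file.path(directory, e$image))
    mask <- png::readPNG(file.path(directory, e$mask))
    if (length(dim(mask)) == 3L) mask <- mask[, , 1L]
    meta <- e[setdiff(names(e), c("image", "mask"))]
    meta$equivDiameters <- unlist(meta$equivDiameters)
    new("SegmentationSample", image = img,
        mask = matrix(as.numeric(mask > 0.5), nrow(mask), ncol(mask)),
        metadata = meta)
  })
  if (!is.null(manifest$spec))
    attr(samples, "spec") <- .specFromList(manifest$spec)
  samples
}

# generic bilinear resize via interpolation matrices (half-pixel centers)
.bilinearResizeMatrix <- function(nOut, nIn) {
  U <- matrix(0, nOut, nIn)
  for (i in seq_len(nOut)) {
    src <- (i - 0.5) * nIn / nOut - 0.5
    j0 <- floor(src)
    w1 <- src - j0
    a <- min(max(j0 + 1, 1L), nIn)
    b <- min(max(j0 + 2, 1L), nIn)
    U[i, a] <- U[i, a] + (1 - w1)
    U[i, b] <- U[i, b] + w1
  }
  U
}

.resizeBilinear <- function(img, hOut, wOut) {
  d <- dim(img)
  Ur <- .bilinearResizeMatrix(hOut, d[1])
  Uc <- .bilinearResizeMatrix(wOut, d[2])
  out <- array(0, c(hOut, wOut, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- Ur %*% img[, , c] %*% t(Uc)
  out
}
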