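#' Render a 2x2 subband decomposition grid
#'
#' Decomposes an image with one DWT level and writes a PNG showing the four
#' subbands in a 2x2 grid (LL top-left, LH top-right, HL bottom-left, HH
#' bottom-right), each panel min-max scaled to [0, 1] for display (flat
#' panels render as 0).
#'
#' @param image matrix, `H x W x C` array (averaged to grayscale), or an
#'   image file path.
#' @param wavelet wavelet name, spec or bank.
#' @param outPath output PNG path.
#' @return invisibly, the [SubbandSet-class].
#' @export
demoDecompose <- function(image, wavelet, outPath) {
  if (is.character(image)) image <- .readImageFile(image)
  if (length(dim(image)) == 3L)
    image <- matrix(rowMeans(matrix(image, prod(dim(image)[1:2]), dim(image)[3])),
                    dim(image)[1], dim(image)[2])
  image <- as.matrix(image)
  d <- dim(image)
  if (d[1] %% 2L || d[2] %% 2L)
    image <- image[seq_len(d[1] - d[1] %% 2L), seq_len(d[2] - d[2] %% 2L)]
  s <- dwt2(image, wavelet)
  scale01 <- function(m) {
    r <- range(m)
    if (diff(r) < .Machine$double.eps) return(m * 0)
    (m - r[1]) / diff(r)
  }
  grid <- rbind(cbind(scale01(s@ll), scale01(s@lh)),
                cbind(scale01(s@hl), scale01(s@hh)))
  png::writePNG(grid, outPath)
  invisible(s)
}
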