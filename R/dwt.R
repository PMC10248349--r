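# Separable one-level periodized 2D-DWT for multi-channel feature maps.
#
# 1D analysis convention (periodization, even phase): for a length-N signal
# x and filter f of length L, y_k = sum_{i=0}^{L-1} f_i x_{(2k+i) mod N},
# k = 0..N/2-1. Synthesis is the adjoint of the same indexing with the
# synthesis filters, which yields perfect reconstruction for every bank in
# the registry. The row pass filters along image width; the column pass
# along height ("first each row, then each column").

# normalize input to H x W x C x N, remembering the original rank
.as4d <- function(x) {
  if (is.null(dim(x))) stop("input must be a matrix or array")
  d <- dim(x)
  nd <- length(d)
  if (nd == 2L) dim(x) <- c(d, 1L, 1L)
  else if (nd == 3L) dim(x) <- c(d, 1L)
  else if (nd != 4L) stop("input must have 2 (H x W), 3 (H x W x C) or 4 (H x W x C x N) dimensions")
  list(x = x, rank = nd)
}

.restoreRank <- function(x, rank) {
  d <- dim(x)
  if (rank == 2L) dim(x) <- d[1:2]
  else if (rank == 3L) dim(x) <- d[1:3]
  x
}

# filter + decimate along height (dim 1), periodized
.colPass <- function(x, f) {
  d <- dim(x); H <- d[1]; K <- H %/% 2L
  out <- array(0, c(K, d[2], d[3], d[4]))
  base <- 2L * (seq_len(K) - 1L)
  for (i in seq_along(f)) {
    idx <- ((base + (i - 1L)) %% H) + 1L
    out <- out + f[i] * x[idx, , , , drop = FALSE]
  }
  out
}

# filter + decimate along width (dim 2), periodized
.rowPass <- function(x, f) {
  d <- dim(x); W <- d[2]; K <- W %/% 2L
  out <- array(0, c(d[1], K, d[3], d[4]))
  base <- 2L * (seq_len(K) - 1L)
  for (i in seq_along(f)) {
    idx <- ((base + (i - 1L)) %% W) + 1L
    out <- out + f[i] * x[, idx, , , drop = FALSE]
  }
  out
}

# adjoints (scatter-add); for a fixed filter tap the target indices are
# distinct, so indexed += is safe
.colAdj <- function(y, f, H) {
  d <- dim(y); K <- d[1]
  x <- array(0, c(H, d[2], d[3], d[4]))
  base <- 2L * (seq_len(K) - 1L)
  for (i in seq_along(f)) {
    idx <- ((base + (i - 1L)) %% H) + 1L
    x[idx, , , ] <- x[idx, , , , drop = FALSE] + f[i] * y
  }
  x
}

.rowAdj <- function(y, f, W) {
  d <- dim(y); K <- d[2]
  x <- array(0, c(d[1], W, d[3], d[4]))
  base <- 2L * (seq_len(K) - 1L)
  for (i in seq_along(f)) {
    idx <- ((base + (i - 1L)) %% W) + 1L
    x[, idx, , ] <- x[, idx, , , drop = FALSE] + f[i] * y
  }
  x
}

.checkDwtInput <- function(x4) {
  d <- dim(x4)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
    stop(sprintf("height and width must be even for one DWT level; got %d x %d", d[1], d[2]))
  if (anyNA(x4) || !all(is.finite(x4)))
    stop("input contains NA/NaN/Inf values")
  invisible(NULL)
}

.asBank <- function(bank) {
  if (is.character(bank) || is(bank, "WaveletSpec")) bank <- buildFilterBank(bank)
  stopifnot(is(bank, "WaveletFilterBank"))
  bank
}

#' One-level 2D discrete wavelet transform
#'
#' Decomposes each channel of a feature map into the four subbands
#' `LL`, `LH`, `HL`, `HH` by separable periodized filtering: a 1D-DWT along
#' each row (width), then along each column (height) of the intermediates.
#' Orientation naming is row-first: `LH` is row high-pass then column
#' low-pass (horizontal detail), `HL` the converse, `HH` diagonal. Output
#' subbands have spatial size exactly `H/2 x W/2`.
#'
#' @param x matrix `H x W`, array `H x W x C`, or batch `H x W x C x N`;
#'   `H` and `W` must be even and all entries finite.
#' @param bank a [WaveletFilterBank-class], a [WaveletSpec-class], or a
#'   wavelet name such as `"haar"`.
#' @return a [SubbandSet-class]; each subband has the same rank as `x`.
#' @examples
#' s <- dwt2(matrix(c(1, 3, 2, 4), 2, 2), "haar")
#' llBand(s)   # 5
#' @export
dwt2 <- function(x, bank) {
  bank <- .asBank(bank)
  g <- .as4d(x)
  .checkDwtInput(g$x)
  l <- bank@analysisLow; h <- bank@analysisHigh
  rowL <- .rowPass(g$x, l)
  rowH <- .rowPass(g$x, h)
  new("SubbandSet",
      ll = .restoreRank(.colPass(rowL, l), g$rank),
      lh = .restoreRank(.colPass(rowH, l), g$rank),
      hl = .restoreRank(.colPass(rowL, h), g$rank),
      hh = .restoreRank(.colPass(rowH, h), g$rank))
}

#' Inverse one-level 2D discrete wavelet transform
#'
#' Reconstructs a feature map from its four subbands with the synthesis
#' filter pair; `idwt2(dwt2(x, b), b)` recovers `x` to numerical precision
#' for every supported bank.
#'
#' @param subbands a [SubbandSet-class].
#' @param bank as in [dwt2()].
#' @return the reconstructed map, `H x W (x C (x N))`.
#' @export
idwt2 <- function(subbands, bank) {
  stopifnot(is(subbands, "SubbandSet"))
  validObject(subbands)
  bank <- .asBank(bank)
  lt <- bank@synthesisLow; ht <- bank@synthesisHigh
  g <- .as4d(subbands@ll)
  rank <- g$rank
  ll <- g$x
  lh <- .as4d(subbands@lh)$x
  hl <- .as4d(subbands@hl)$x
  hh <- .as4d(subbands@hh)$x
  H <- 2L * dim(ll)[1]; W <- 2L * dim(ll)[2]
  rowL <- .colAdj(ll, lt, H) + .colAdj(hl, ht, H)
  rowH <- .colAdj(lh, lt, H) + .colAdj(hh, ht, H)
  .restoreRank(.rowAdj(rowL, lt, W) + .rowAdj(rowH, ht, W), rank)
}

#' Wavelet downsampling (LL-only)
#'
#' The downsampling operator of the network: one DWT level per channel,
#' keeping only the low-frequency `LL` subband and discarding the three
#' detail subbands (treated as noise). Halves height and width; channel
#' count is unchanged. The operator is linear, so gradients propagate
#' through its adjoint (transposed filtering).
#'
#' @inheritParams dwt2
#' @return the `LL` subband, spatial size `H/2 x W/2`.
#' @examples
#' x <- array(1, c(4, 4, 2))
#' waveletDownsample(x, "haar")[1, 1, 1]  # a constant c maps to 2c
#' @export
waveletDownsample <- function(x, bank) {
  bank <- .asBank(bank)
  g <- .as4d(x)
  .checkDwtInput(g$x)
  l <- bank@analysisLow
  .restoreRank(.colPass(.rowPass(g$x, l), l), g$rank)
}

# gradient of waveletDownsample: adjoint of the LL analysis path
.waveletDownsampleBackward <- function(dLL, bank, H, W) {
  l <- bank@analysisLow
  .rowAdj(.colAdj(dLL, l, H), l, W)
}

#' @describeIn subbandAccessors low-frequency approximation band
#' @export
llBand <- function(s) s@ll
#' @describeIn subbandAccessors horizontal-detail band (row high-pass)
#' @export
lhBand <- function(s) s@lh
#' @describeIn subbandAccessors vertical-detail band (column high-pass)
#' @export
hlBand <- function(s) s@hl
#' Subband accessors
#'
#' @param s a [SubbandSet-class].
#' @return the requested subband array.
#' @name subbandAccessors
#' @describeIn subbandAccessors diagonal-detail band
#' @export
hhBand <- function(s) s@hh

setMethod("show", "SubbandSet", function(object) {
  cat("SubbandSet:", paste(dim(object@ll), collapse = " x "),
      "per subband (LL/LH/HL/HH)\n")
})
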