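#' Create residual attention gate parameters
#'
#' The gate projects the decoder (gating) feature and the encoder (skip)
#' feature to a common intermediate channel count with 1x1 convolutions
#' (biases included), optionally batch-normalizes each branch, adds them,
#' applies ReLU, reduces to one channel with a third 1x1 convolution and
#' squashes with a sigmoid. The intermediate channel count equals the skip
#' feature's channel count.
#'
#' @param gatingChannels channels of the gating feature `x_g`.
#' @param skipChannels channels of the skip feature `x_l`; also the
#'   intermediate channel count.
#' @param seed RNG seed for the Kaiming-uniform projections.
#' @param normalize include per-branch batch normalization (identity affine,
#'   zero/unit running statistics at creation). Set `FALSE` for exact
#'   hand-computable arithmetic.
#' @return a named list of parameter arrays, editable in place.
#' @export
attentionParams <- function(gatingChannels, skipChannels,
                            seed = 1L, normalize = TRUE) {
  set.seed(as.integer(seed))
  fInt <- as.integer(skipChannels)
  if (fInt < 1L) stop("skipChannels must be >= 1")
  wg <- .initConv(1L, gatingChannels, fInt)
  wl <- .initConv(1L, skipChannels, fInt)
  psi <- .initConv(1L, fInt, 1L)
  p <- list(wg = wg$w, wgB = wg$b, wl = wl$w, wlB = wl$b,
            psi = psi$w, psiB = psi$b, normalize = isTRUE(normalize))
  if (p$normalize) {
    p$bngG <- rep(1, fInt); p$bngB <- rep(0, fInt)
    p$bngRM <- rep(0, fInt); p$bngRV <- rep(1, fInt)
    p$bnlG <- rep(1, fInt); p$bnlB <- rep(0, fInt)
    p$bnlRM <- rep(0, fInt); p$bnlRV <- rep(1, fInt)
  }
  p
}

.attnBranch <- function(x, w, b, g, be, rm, rv, normalize) {
  q <- .conv(x, w, b, 1L, 0L)
  if (normalize) q <- .bnF(q, g, be, rm, rv, training = FALSE)$y
  q
}

#' Attention coefficients
#'
#' Computes the per-pixel attention map
#' `alpha = sigmoid(psi^T relu(W_g x_g + W_l x_l))` (with optional
#' per-branch normalization between projection and summation). All values
#' lie strictly in (0, 1) by construction of the sigmoid.
#'
#' @param xg gating feature from the decoder, `H x W x Cg (x N)`.
#' @param xl skip feature from the encoder, `H x W x Cl (x N)`; must share
#'   the spatial size of `xg` (the caller upsamples the decoder feature
#'   first).
#' @param params from [attentionParams()].
#' @return single-channel array of attention coefficients in (0, 1), same
#'   spatial size and rank as `xl`.
#' @export
attentionCoefficients <- function(xg, xl, params) {
  gg <- .as4d(xg); gl <- .as4d(xl)
  dg <- dim(gg$x); dl <- dim(gl$x)
  if (dg[1] != dl[1] || dg[2] != dl[2])
    stop(sprintf("spatial sizes differ: gating %d x %d vs skip %d x %d",
                 dg[1], dg[2], dl[1], dl[2]))
  if (dg[4] != dl[4]) stop("batch sizes differ")
  nrm <- isTRUE(params$normalize)
  qg <- .attnBranch(gg$x, params$wg, params$wgB, params$bngG, params$bngB,
                    params$bngRM, params$bngRV, nrm)
  ql <- .attnBranch(gl$x, params$wl, params$wlB, params$bnlG, params$bnlB,
                    params$bnlRM, params$bnlRV, nrm)
  s <- pmax(qg + ql, 0)
  z <- .conv(s, params$psi, params$psiB, 1L, 0L)
  .restoreRank(.sigmoid(z), gl$rank)
}

#' Residual attention gate forward
#'
#' Recalibrates the skip feature and adds it back:
#' `x_o = alpha * x_l + x_l = (1 + alpha) * x_l`, with the single-channel
#' `alpha` broadcast across all channels of `x_l`. Because
#' `alpha` is in (0, 1), the output is elementwise between `x_l` and
#' `2 x_l` wherever `x_l > 0`.
#'
#' @inheritParams attentionCoefficients
#' @return list with `output` (same shape as `xl`), `alpha`, and
#'   `recalibrated` (`alpha * x_l`).
#' @export
ramForward <- function(xg, xl, params) {
  a <- attentionCoefficients(xg, xl, params)
  gl <- .as4d(xl)
  a4 <- .as4d(a)$x
  C <- dim(gl$x)[3]
  ab <- a4[, , rep(1L, C), , drop = FALSE]
  rec <- gl$x * ab
  list(output = .restoreRank(gl$x + rec, gl$rank),
       alpha = a,
       recalibrated = .restoreRank(rec, gl$rank))
}
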