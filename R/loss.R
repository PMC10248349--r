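#' Hybrid loss configuration
#'
#' @param alphaWeight weight of the binary cross-entropy term (default 0.4).
#' @param betaWeight weight of the Dice term (default 0.6).
#' @param lambdaSmooth Dice smoothing factor added to the denominator to
#'   keep it positive (default 1).
#' @param clampEps probabilities are clamped to `[eps, 1 - eps]` before
#'   logarithms (default 1e-7).
#' @return a [LossConfig-class].
#' @export
lossConfig <- function(alphaWeight = 0.4, betaWeight = 0.6,
                       lambdaSmooth = 1, clampEps = 1e-7) {
  new("LossConfig", alphaWeight = alphaWeight, betaWeight = betaWeight,
      lambdaSmooth = lambdaSmooth, clampEps = clampEps)
}

.checkPY <- function(p, y) {
  if (length(p) != length(y) || !identical(dim(p), dim(y)))
    stop("prediction and mask shapes differ")
  if (!all(y %in% c(0, 1))) stop("mask values must lie in {0, 1}")
  invisible(NULL)
}

#' Binary cross-entropy loss
#'
#' `-(1/n) sum(y log p + (1 - y) log(1 - p))` averaged over all pixels,
#' with `p` clamped away from 0 and 1.
#'
#' @param p predicted probabilities (any numeric array).
#' @param y binary ground-truth mask, same shape.
#' @param clampEps clamping bound for the logarithms.
#' @return scalar loss.
#' @examples
#' bceLoss(rep(0.5, 10), rep(c(0, 1), 5))  # log(2)
#' @export
bceLoss <- function(p, y, clampEps = 1e-7) {
  .checkPY(p, y)
  pc <- pmin(pmax(p, clampEps), 1 - clampEps)
  -mean(y * log(pc) + (1 - y) * log(1 - pc))
}

#' Soft Dice loss
#'
#' `1 - 2 sum(p y) / (sum(p + y) + lambda)` on soft probabilities (no
#' thresholding). Note the documented degeneracy: on a perfectly predicted
#' empty mask the numerator is zero and the loss equals 1.
#'
#' @inheritParams bceLoss
#' @param lambdaSmooth smoothing factor in the denominator.
#' @return scalar loss.
#' @examples
#' diceLoss(rep(1, 100), rep(1, 100), lambdaSmooth = 1)  # 1 - 200/201
#' @export
diceLoss <- function(p, y, lambdaSmooth = 1) {
  .checkPY(p, y)
  1 - 2 * sum(p * y) / (sum(p + y) + lambdaSmooth)
}

#' Hybrid BCE + Dice loss
#'
#' `alpha * L_BCE + beta * L_Dice` with default weights `alpha = 0.4`,
#' `beta = 0.6`.
#'
#' @inheritParams bceLoss
#' @param cfg a [LossConfig-class].
#' @return scalar loss.
#' @export
hybridLoss <- function(p, y, cfg = lossConfig()) {
  stopifnot(is(cfg, "LossConfig"))
  validObject(cfg)
  cfg@alphaWeight * bceLoss(p, y, cfg@clampEps) +
    cfg@betaWeight * diceLoss(p, y, cfg@lambdaSmooth)
}

# loss + gradient wrt p, for the training loop. kind restricts to one term.
.lossWithGrad <- function(p, y, cfg, kind = "hybrid") {
  n <- length(p)
  eps <- cfg@clampEps
  pc <- pmin(pmax(p, eps), 1 - eps)
  inner <- !(p < eps | p > 1 - eps)   # clamped pixels get zero BCE gradient
  lb <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  gb <- -(y / pc - (1 - y) / (1 - pc)) / n * inner
  I <- sum(p * y)
  D <- sum(p + y) + cfg@lambdaSmooth
  ld <- 1 - 2 * I / D
  gd <- -(2 * y * D - 2 * I) / D^2
  switch(kind,
    bce    = list(loss = lb, grad = gb),
    dice   = list(loss = ld, grad = gd),
    hybrid = list(loss = cfg@alphaWeight * lb + cfg@betaWeight * ld,
                  grad = cfg@alphaWeight * gb + cfg@betaWeight * gd))
}
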