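#' Segmentation metrics
#'
#' Binarizes predictions at `threshold`, computes TP/FP/FN/TN per image and
#' the four overlap metrics: Dice `2|G.P| / (|G| + |P|)`, IoU
#' `|G.P| / |G u P|`, precision `TP / (TP + FP)` and sensitivity
#' `TP / (TP + FN)`. With `aggregate = "macro"` (default) metrics are
#' computed per image and averaged; `"micro"` pools the counts first.
#' Empty-denominator convention: if ground truth and prediction are both
#' empty all four metrics are 1; if exactly one is empty they are 0.
#'
#' @param pred probability map(s): matrix, `H x W x 1 (x N)` array, or a
#'   list of matrices. Already-binary masks are accepted.
#' @param gt ground-truth binary mask(s) of matching shape.
#' @param threshold binarization threshold in `(0, 1)`, default 0.5.
#' @param aggregate `"macro"` or `"micro"`.
#' @return a [MetricsReport-class].
#' @examples
#' g <- matrix(0, 4, 4); g[1:2, 1:2] <- 1
#' metrics(g, g)        # all ones
#' @export
metrics <- function(pred, gt, threshold = 0.5, aggregate = c("macro", "micro")) {
  aggregate <- match.arg(aggregate)
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  toList <- function(x) {
    if (is.list(x)) return(lapply(x, as.matrix))
    d <- dim(x)
    if (is.null(d) || length(d) == 2L) return(list(as.matrix(x)))
    if (length(d) == 3L) x <- array(x, c(d, 1L))
    d <- dim(x)
    lapply(seq_len(d[4]), function(n) matrix(x[, , 1L, n], d[1], d[2]))
  }
  ps <- toList(pred); gs <- toList(gt)
  if (length(ps) != length(gs)) stop("prediction and mask counts differ")
  perImage <- lapply(seq_along(ps), function(i) {
    if (anyNA(ps[[i]]) || anyNA(gs[[i]]))
      stop(sprintf("prediction or mask %d contains NA/NaN", i))
    p <- ps[[i]] >= threshold
    g <- gs[[i]] >= 0.5
    if (!identical(dim(p), dim(g))) stop("prediction and mask shapes differ")
    tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)
    c(tp = tp, fp = fp, fn = fn, tn = tn)
  })
  cnt <- do.call(rbind, perImage)
  metricFromCounts <- function(tp, fp, fn) {
    tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
    nG <- tp + fn; nP <- tp + fp
    if (nG == 0 && nP == 0) return(c(dice = 1, iou = 1, precision = 1, sensitivity = 1))
    if (nG == 0 || nP == 0) return(c(dice = 0, iou = 0, precision = 0, sensitivity = 0))
    c(dice = 2 * tp / (nG + nP), iou = tp / (tp + fp + fn),
      precision = tp / nP, sensitivity = tp / nG)
  }
  if (aggregate == "macro") {
    m <- colMeans(do.call(rbind, lapply(seq_len(nrow(cnt)), function(i)
      metricFromCounts(cnt[i, "tp"], cnt[i, "fp"], cnt[i, "fn"]))))
  } else {
    m <- metricFromCounts(sum(cnt[, "tp"]), sum(cnt[, "fp"]), sum(cnt[, "fn"]))
  }
  new("MetricsReport",
      dice = unname(m["dice"]), iou = unname(m["iou"]),
      precision = unname(m["precision"]), sensitivity = unname(m["sensitivity"]),
      tp = sum(cnt[, "tp"]), fp = sum(cnt[, "fp"]),
      fn = sum(cnt[, "fn"]), tn = sum(cnt[, "tn"]),
      nImages = length(ps), aggregate = aggregate)
}

#' Serialize a metrics report to JSON
#'
#' Metric values are fractions in `[0, 1]`; raw confusion counts included.
#'
#' @param report a [MetricsReport-class].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
metricsToJSON <- function(report, path = NULL) {
  stopifnot(is(report, "MetricsReport"))
  x <- list(dice = report@dice, iou = report@iou,
            precision = report@precision, sensitivity = report@sensitivity,
            tp = report@tp, fp = report@fp, fn = report@fn, tn = report@tn,
            n_images = report@nImages, aggregate = report@aggregate)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport (%s over %d image%s):\n", object@aggregate,
              object@nImages, if (object@nImages == 1L) "" else "s"))
  cat(sprintf("  Dice %.4f | IoU %.4f | PR %.4f | SE %.4f\n",
              object@dice, object@iou, object@precision, object@sensitivity))
  cat(sprintf("  counts: TP %d FP %d FN %d TN %d\n",
              as.integer(object@tp), as.integer(object@fp),
              as.integer(object@fn), as.integer(object@tn)))
})
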