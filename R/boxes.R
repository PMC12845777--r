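# Box geometry: IoU, complete IoU and greedy non-maximum suppression.
# Boxes are rows (x1, y1, x2, y2) in pixels with x2 > x1, y2 > y1.

#' Pairwise intersection-over-union between two box sets
#'
#' @param a,b numeric matrices with columns x1, y1, x2, y2.
#' @return a `nrow(a)` x `nrow(b)` matrix of IoU values.
#' @export
box_iou <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 4)
  b <- matrix(as.numeric(b), ncol = 4)
  ix1 <- outer(a[, 1], b[, 1], pmax); iy1 <- outer(a[, 2], b[, 2], pmax)
  ix2 <- outer(a[, 3], b[, 3], pmin); iy2 <- outer(a[, 4], b[, 4], pmin)
  iw <- pmax(ix2 - ix1, 0); ih <- pmax(iy2 - iy1, 0)
  inter <- iw * ih
  aa <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  ab <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  inter / (outer(aa, ab, `+`) - inter + 1e-12)
}

#' Complete IoU between two boxes
#'
#' IoU minus the normalised centre distance and an aspect-ratio consistency
#' term: `CIoU = IoU - rho^2 / c^2 - alpha * v` with
#' `v = (4 / pi^2) (atan(w2/h2) - atan(w1/h1))^2` and
#' `alpha = v / (1 - IoU + v)`.
#'
#' @param p,g numeric length-4 vectors (x1, y1, x2, y2).
#' @return scalar CIoU in (-1, 1].
#' @export
ciou <- function(p, g) {
  iou <- box_iou(matrix(p, 1), matrix(g, 1))[1, 1]
  wp <- p[3] - p[1]; hp <- p[4] - p[2]
  wg <- g[3] - g[1]; hg <- g[4] - g[2]
  cxp <- (p[1] + p[3]) / 2; cyp <- (p[2] + p[4]) / 2
  cxg <- (g[1] + g[3]) / 2; cyg <- (g[2] + g[4]) / 2
  rho2 <- (cxp - cxg)^2 + (cyp - cyg)^2
  cw <- max(p[3], g[3]) - min(p[1], g[1])
  chh <- max(p[4], g[4]) - min(p[2], g[2])
  c2 <- cw^2 + chh^2 + 1e-12
  v <- 4 / pi^2 * (atan(wg / (hg + 1e-12)) - atan(wp / (hp + 1e-12)))^2
  alpha <- v / (1 - iou + v + 1e-12)
  iou - rho2 / c2 - alpha * v
}

#' Greedy per-class non-maximum suppression
#'
#' Keeps detections in descending score order, dropping any same-class box
#' whose IoU with an already kept box exceeds `iou_thresh`; detections below
#' `conf_thresh` are discarded first.  Survivors are returned sorted by
#' descending score.
#'
#' @param dets data.frame with columns x1, y1, x2, y2, score, class (and any
#'   extra columns, preserved).
#' @param iou_thresh,conf_thresh thresholds in `[0, 1]`.
#' @export
nms <- function(dets, iou_thresh = 0.45, conf_thresh = 0.25) {
  stopifnot(iou_thresh >= 0, iou_thresh <= 1, conf_thresh >= 0,
            conf_thresh <= 1)
  dets <- dets[dets$score >= conf_thresh, , drop = FALSE]
  if (nrow(dets) == 0) return(dets)
  dets <- dets[order(-dets$score), , drop = FALSE]
  keep <- logical(nrow(dets))
  boxes <- as.matrix(dets[, c("x1", "y1", "x2", "y2")])
  for (i in seq_len(nrow(dets))) {
    prev <- which(keep & dets$class == dets$class[i])
    if (length(prev) == 0 ||
        all(box_iou(boxes[i, , drop = FALSE],
                    boxes[prev, , drop = FALSE]) <= iou_thresh))
      keep[i] <- TRUE
  }
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
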