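# Detection metrics: precision, recall, average precision with 101-point
# interpolation, and the IoU-swept mean average precision (0.5 to 0.95 in
# steps of 0.05).

# Greedy one-to-one matching of predictions (descending score) to ground
# truths of the same class and image at IoU >= thr; each pick takes the
# highest-IoU still-unmatched truth.  Returns the TP flag per prediction.
match_predictions <- function(pred, truth, thr) {
  tp <- logical(nrow(pred))
  if (nrow(truth) == 0 || nrow(pred) == 0) return(tp)
  used <- logical(nrow(truth))
  pb <- as.matrix(pred[, c("x1", "y1", "x2", "y2")])
  tb <- as.matrix(truth[, c("x1", "y1", "x2", "y2")])
  iou <- box_iou(pb, tb)
  for (i in seq_len(nrow(pred))) {
    ok <- which(!used & truth$image == pred$image[i] & iou[i, ] >= thr)
    if (length(ok)) {
      j <- ok[which.max(iou[i, ok])]
      used[j] <- TRUE
      tp[i] <- TRUE
    }
  }
  tp
}

# 101-point interpolated area under the precision-recall curve.
ap_101 <- function(tp, n_truth) {
  if (n_truth == 0) return(0)
  if (length(tp) == 0) return(0)
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  recall <- cum_tp / n_truth
  precision <- cum_tp / (cum_tp + cum_fp)
  grid <- seq(0, 1, by = 0.01)
  mean(vapply(grid, function(r) {
    ok <- recall >= r
    if (any(ok)) max(precision[ok]) else 0
  }, numeric(1)))
}

#' Mean average precision over an IoU threshold sweep
#'
#' AP per class is the 101-point interpolated area under the
#' precision-recall curve built from greedy highest-score-first one-to-one
#' matching at each IoU threshold; `mAP@0.5` averages AP over classes at
#' IoU 0.5 and `mAP@0.5:0.95` additionally averages over thresholds 0.5 to
#' 0.95 in steps of 0.05.  A class predicted but absent from the ground
#' truth contributes AP 0 with a warning.
#'
#' @param preds data.frame with columns image, x1, y1, x2, y2, score, class.
#' @param truths data.frame with columns image, x1, y1, x2, y2, class.
#' @param iou_grid IoU thresholds of the sweep.
#' @return a `map_result` with `map50`, `map5095`, and the class-by-threshold
#'   AP matrix `ap`.
#' @export
evaluate_map <- function(preds, truths, iou_grid = seq(0.5, 0.95, by = 0.05)) {
  classes <- sort(unique(c(preds$class, truths$class)))
  ghost <- setdiff(unique(preds$class), unique(truths$class))
  if (length(ghost))
    warning("predicted class(es) with no ground truth: ",
            paste(ghost, collapse = ", "), " (AP 0)", call. = FALSE)
  ap <- matrix(0, nrow = length(classes), ncol = length(iou_grid),
               dimnames = list(classes, sprintf("iou%.2f", iou_grid)))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    p <- preds[preds$class == cl, , drop = FALSE]
    p <- p[order(-p$score), , drop = FALSE]
    t <- truths[truths$class == cl, , drop = FALSE]
    for (ti in seq_along(iou_grid))
      ap[ci, ti] <- ap_101(match_predictions(p, t, iou_grid[ti]), nrow(t))
  }
  structure(list(map50 = mean(ap[, 1]), map5095 = mean(ap), ap = ap,
                 classes = classes, iou_grid = iou_grid),
            class = "map_result")
}

#' @export
print.map_result <- function(x, ...) {
  cat(sprintf("<map_result> mAP@0.5 = %.4f  mAP@0.5:0.95 = %.4f  (%d classes)\n",
              x$map50, x$map5095, length(x$classes)))
  invisible(x)
}

#' Precision and recall of a matched detection set
#'
#' `recall = TP / (TP + FN)` and `precision = TP / (TP + FP)` at a single
#' IoU threshold, over all classes.
#'
#' @inheritParams evaluate_map
#' @param iou_thresh matching threshold.
#' @export
precision_recall <- function(preds, truths, iou_thresh = 0.5) {
  tp_total <- 0L
  for (cl in unique(truths$class)) {
    p <- preds[preds$class == cl, , drop = FALSE]
    p <- p[order(-p$score), , drop = FALSE]
    t <- truths[truths$class == cl, , drop = FALSE]
    tp_total <- tp_total + sum(match_predictions(p, t, iou_thresh))
  }
  list(precision = if (nrow(preds)) tp_total / nrow(preds) else 0,
       recall = if (nrow(truths)) tp_total / nrow(truths) else 0)
}
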