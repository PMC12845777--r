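# Decoding raw head outputs into detections.  Contract per scale: a grid of
# 3 anchors x (4 box + 1 objectness + nc class) values; sigmoid on xy,
# objectness and class logits; xy = (2*sigmoid(t) - 0.5 + cell) * stride;
# wh = (2*sigmoid(t))^2 * anchor (pixels).

decode_scale <- function(h, anchors, stride, nc) {
  no <- nc + 5L
  d <- dim(h)
  Hg <- d[2]; Wg <- d[3]
  arr <- array(h, c(no, 3L, Hg, Wg))
  s <- function(j) sigmoid_arr(arr[j, , , , drop = FALSE])
  gx <- array(rep(0:(Wg - 1), each = 3 * Hg), c(1, 3, Hg, Wg))
  gy <- array(rep(rep(0:(Hg - 1), each = 3), times = Wg), c(1, 3, Hg, Wg))
  aw <- array(anchors[, 1], c(1, 3, Hg, Wg))
  ah <- array(anchors[, 2], c(1, 3, Hg, Wg))
  px <- (2 * s(1) - 0.5 + gx) * stride
  py <- (2 * s(2) - 0.5 + gy) * stride
  pw <- (2 * s(3))^2 * aw
  ph <- (2 * s(4))^2 * ah
  obj <- as.vector(s(5))
  cls <- matrix(sigmoid_arr(arr[5L + seq_len(nc), , , , drop = FALSE]),
                nrow = nc)
  best <- max.col(t(cls))
  best_p <- cls[cbind(best, seq_along(best))]
  data.frame(x1 = as.vector(px - pw / 2), y1 = as.vector(py - ph / 2),
             x2 = as.vector(px + pw / 2), y2 = as.vector(py + ph / 2),
             score = obj * best_p, class = best - 1L)
}

#' Decode raw head outputs into a detection table
#'
#' @param model a `gefay_model`.
#' @param heads list of three raw head arrays from [model_forward()].
#' @param conf_thresh minimum decoded score to keep (pre-NMS).
#' @return data.frame with x1, y1, x2, y2 (pixels), score, class (0-based).
#' @export
decode_heads <- function(model, heads, conf_thresh = 0.001) {
  out <- lapply(1:3, function(s)
    decode_scale(heads[[s]], model$spec$anchors[[s]], model$strides[s],
                 model$spec$nc))
  out <- do.call(rbind, out)
  out[out$score >= conf_thresh, , drop = FALSE]
}

#' Detect objects in an image
#'
#' Runs the detector forward, decodes and applies per-class NMS.
#'
#' @param model a `gefay_model`.
#' @param image a `c(3, H, W)` array in `[0, 1]` or a PNG file path.
#' @param conf,iou confidence and NMS IoU thresholds.
#' @param batch_stats normalise with the statistics of this image rather
#'   than the running averages (the consistent choice when the model was
#'   trained with single-image batches).
#' @export
detect <- function(model, image, conf = 0.25, iou = 0.45,
                   batch_stats = FALSE) {
  if (is.character(image)) image <- read_image_chw(image)
  heads <- model_forward(model, image, train = batch_stats)
  dets <- decode_heads(model, heads, conf_thresh = conf / 4)
  dets$image <- 1L
  nms(dets, iou_thresh = iou, conf_thresh = conf)
}
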