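# Base-graphics visualisation helpers.

#' Plot a training history
#'
#' Loss (left axis) and validation mAP@0.5 (right axis) against epoch.
#'
#' @param history data.frame from [train()].
#' @export
plot_history <- function(history) {
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(history$epoch, history$loss, type = "l", lwd = 2,
                 xlab = "epoch", ylab = "training loss", col = "firebrick")
  graphics::par(new = TRUE)
  graphics::plot(history$epoch, history$val_map50, type = "l", lwd = 2,
                 col = "steelblue", axes = FALSE, xlab = "", ylab = "",
                 ylim = c(0, 1))
  graphics::axis(4)
  graphics::mtext("val mAP@0.5", side = 4, line = 2.5)
  invisible(history)
}

#' Plot an image with detection boxes
#'
#' @param img array `c(3, H, W)` in `[0, 1]`.
#' @param dets data.frame of detections (x1, y1, x2, y2, score, class).
#' @param truths optional truth boxes drawn dashed.
#' @export
plot_detections <- function(img, dets = NULL, truths = NULL) {
  d <- dim(img)
  graphics::plot(NA, xlim = c(0, d[3]), ylim = c(d[2], 0), asp = 1,
                 xlab = "", ylab = "", axes = FALSE)
  graphics::rasterImage(aperm(img, c(2, 3, 1)), 0, d[2], d[3], 0)
  draw <- function(df, lty) {
    if (is.null(df) || !nrow(df)) return()
    for (i in seq_len(nrow(df)))
      graphics::rect(df$x1[i], df$y2[i], df$x2[i], df$y1[i],
                     border = grDevices::hsv((df$class[i] + 0.5) / 12, 1, 1),
                     lwd = 2, lty = lty)
  }
  draw(dets, 1)
  draw(truths, 2)
  invisible(NULL)
}
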