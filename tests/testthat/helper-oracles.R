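# Independent oracles used across the suite.  These deliberately share no
# code with the package implementations they check.

# Plain-loop block-mean pooling.
oracle_block_mean <- function(x, p) {
  d <- dim(x)
  bh <- floor((0:p) * d[2] / p); bw <- floor((0:p) * d[3] / p)
  y <- array(0, c(d[1], p, p))
  for (c in seq_len(d[1]))
    for (i in seq_len(p))
      for (j in seq_len(p)) {
        acc <- 0; n <- 0
        for (h in (bh[i] + 1):bh[i + 1])
          for (w in (bw[j] + 1):bw[j + 1]) {
            acc <- acc + x[c, h, w]; n <- n + 1
          }
        y[c, i, j] <- acc / n
      }
  y
}

# Plain-loop nearest-neighbour expansion.
oracle_expand <- function(w, H, W) {
  d <- dim(w); p <- d[2]
  bh <- floor((0:p) * H / p); bw <- floor((0:p) * W / p)
  y <- array(0, c(d[1], H, W))
  for (c in seq_len(d[1]))
    for (h in seq_len(H))
      for (wd in seq_len(W)) {
        i <- max(which(bh < h)); j <- max(which(bw < wd))
        y[c, h, wd] <- w[c, i, j]
      }
  y
}

# Plain-loop zero-padded 1-D convolution along the channel axis.
oracle_chanmix <- function(x, w) {
  d <- dim(x); C <- d[1]
  xm <- matrix(x, nrow = C)
  k <- length(w); h <- (k - 1) / 2
  y <- matrix(0, C, ncol(xm))
  for (c in seq_len(C))
    for (m in seq_len(ncol(xm)))
      for (o in -h:h) {
        s <- c + o
        if (s >= 1 && s <= C) y[c, m] <- y[c, m] + w[o + h + 1] * xm[s, m]
      }
  array(y, d)
}

# Exhaustive NMS: enumerate candidates in score order, checking every kept
# box (no early exit tricks shared with the implementation).
oracle_nms <- function(dets, iou_thresh, conf_thresh) {
  dets <- dets[dets$score >= conf_thresh, , drop = FALSE]
  dets <- dets[order(-dets$score), , drop = FALSE]
  kept <- list()
  for (i in seq_len(nrow(dets))) {
    ok <- TRUE
    for (k in seq_along(kept)) {
      if (kept[[k]]$class != dets$class[i]) next
      a <- unlist(dets[i, c("x1", "y1", "x2", "y2")])
      b <- unlist(kept[[k]][c("x1", "y1", "x2", "y2")])
      ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
      iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
      inter <- ix * iy
      un <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) -
        inter
      if (inter / un > iou_thresh) { ok <- FALSE; break }
    }
    if (ok) kept[[length(kept) + 1L]] <- as.list(dets[i, ])
  }
  do.call(rbind, lapply(kept, as.data.frame))
}

# Independent mean-average-precision: per threshold, build the full
# precision envelope over all operating points and integrate it exactly
# (trapezoid-free step integral of the monotone envelope), instead of
# sampling a fixed recall grid.
oracle_map <- function(preds, truths, iou_grid = seq(0.5, 0.95, 0.05)) {
  classes <- sort(unique(c(preds$class, truths$class)))
  iou1 <- function(a, b) {
    ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- ix * iy
    inter / ((a[3] - a[1]) * (a[4] - a[2]) +
             (b[3] - b[1]) * (b[4] - b[2]) - inter)
  }
  ap_one <- function(p, t, thr) {
    if (nrow(t) == 0) return(0)
    p <- p[order(-p$score), , drop = FALSE]
    used <- logical(nrow(t))
    tp <- logical(nrow(p))
    for (i in seq_len(nrow(p))) {
      best <- 0; bj <- 0
      for (j in seq_len(nrow(t))) {
        if (used[j] || t$image[j] != p$image[i]) next
        v <- iou1(unlist(p[i, c("x1", "y1", "x2", "y2")]),
                  unlist(t[j, c("x1", "y1", "x2", "y2")]))
        if (v >= thr && v > best) { best <- v; bj <- j }
      }
      if (bj > 0) { used[bj] <- TRUE; tp[i] <- TRUE }
    }
    rec <- cumsum(tp) / nrow(t)
    prec <- cumsum(tp) / seq_along(tp)
    # 101-point sampling of the running-max envelope, computed backwards
    env <- rev(cummax(rev(prec)))
    mean(vapply(seq(0, 1, 0.01), function(r) {
      i <- which(rec >= r - 1e-12)
      if (length(i)) env[min(i)] else 0
    }, numeric(1)))
  }
  ap <- sapply(iou_grid, function(thr)
    vapply(classes, function(cl)
      ap_one(preds[preds$class == cl, , drop = FALSE],
             truths[truths$class == cl, , drop = FALSE], thr), numeric(1)))
  ap <- matrix(ap, nrow = length(classes))
  list(map50 = mean(ap[, 1]), map5095 = mean(ap))
}

rand_fmap <- function(C, H, W, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(C * H * W), c(C, H, W))
}
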