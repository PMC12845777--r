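# Composite detection loss: box term (1 - complete IoU) over assigned
# anchors, objectness binary cross-entropy over every cell (with an
# IoU-valued target at assigned cells), and class binary cross-entropy at
# assigned cells.  Assignment follows the multi-anchor convention of the
# baseline family: an anchor matches a truth box when the elementwise
# width/height ratio (either way) stays below `anchor_t`, and the match is
# replicated into the two nearest neighbouring cells.
#
# The gradient of the smooth-overlap box term with respect to the four raw
# logits is obtained by central finite differences of the scalar
# CIoU-of-decoded-box function (8 cheap evaluations per assigned box); all
# cross-entropy gradients are analytic.

bce_logit <- function(t, y) pmax(t, 0) - t * y + log1p(exp(-abs(t)))

#' Validate a YOLO-format label matrix
#'
#' @param labels numeric matrix with columns class, cx, cy, w, h (normalised).
#' @param nc class count; `file` label source named in error messages.
#' @export
validate_labels <- function(labels, nc, file = "<labels>") {
  if (is.null(labels) || length(labels) == 0)
    return(matrix(numeric(0), ncol = 5))
  labels <- matrix(as.numeric(labels), ncol = 5)
  for (i in seq_len(nrow(labels))) {
    r <- labels[i, ]
    if (r[1] < 0 || r[1] >= nc || r[1] != floor(r[1]))
      stop(file, " line ", i, ": class id ", r[1], " outside [0, ", nc, ")",
           call. = FALSE)
    if (any(r[2:5] < 0) || any(r[2:5] > 1))
      stop(file, " line ", i, ": coordinates outside [0, 1]", call. = FALSE)
  }
  labels
}

# Assignment of truth boxes to (anchor, cell) slots on one scale.
build_targets_scale <- function(labels, anchors_grid, Hg, Wg, anchor_t) {
  out <- list()
  if (nrow(labels) == 0) return(out)
  for (li in seq_len(nrow(labels))) {
    cl <- labels[li, 1]
    gx <- labels[li, 2] * Wg; gy <- labels[li, 3] * Hg
    gw <- labels[li, 4] * Wg; gh <- labels[li, 5] * Hg
    if (gw <= 0 || gh <= 0) next
    for (a in seq_len(nrow(anchors_grid))) {
      r <- c(gw, gh) / anchors_grid[a, ]
      if (max(r, 1 / r) >= anchor_t) next
      offs <- list(c(0, 0))
      fx <- gx %% 1; fy <- gy %% 1
      if (fx < 0.5 && gx > 1) offs <- c(offs, list(c(-1, 0)))
      if (fx > 0.5 && gx < Wg - 1) offs <- c(offs, list(c(1, 0)))
      if (fy < 0.5 && gy > 1) offs <- c(offs, list(c(0, -1)))
      if (fy > 0.5 && gy < Hg - 1) offs <- c(offs, list(c(0, 1)))
      for (o in offs) {
        gi <- floor(gx) + o[1]; gj <- floor(gy) + o[2]
        if (gi < 0 || gi >= Wg || gj < 0 || gj >= Hg) next
        out[[length(out) + 1L]] <- c(a = a, gi = gi, gj = gj, gx = gx,
                                     gy = gy, gw = gw, gh = gh, cl = cl)
      }
    }
  }
  out
}

decode_box_grid <- function(t4, gi, gj, anchor) {
  sxy <- 1 / (1 + exp(-t4[1:2]))
  swh <- 1 / (1 + exp(-t4[3:4]))
  px <- 2 * sxy[1] - 0.5 + gi; py <- 2 * sxy[2] - 0.5 + gj
  pw <- (2 * swh[1])^2 * anchor[1]; ph <- (2 * swh[2])^2 * anchor[2]
  c(px - pw / 2, py - ph / 2, px + pw / 2, py + ph / 2)
}

#' Detection loss and head gradients for one image
#'
#' @param model a `gefay_model`.
#' @param heads raw head outputs from a forward pass at the label's image.
#' @param labels validated label matrix (class, cx, cy, w, h).
#' @param cfg a [train_config()] supplying the loss gains.
#' @return list with `loss`, `components` (box/obj/cls) and `dheads`, the
#'   gradient of the loss w.r.t. each raw head array.
#' @export
detection_loss <- function(model, heads, labels, cfg = train_config()) {
  nc <- model$spec$nc
  no <- nc + 5L
  eps_fd <- 1e-4
  lbox <- 0; lcls <- 0; lobj <- 0
  matches_all <- vector("list", 3)
  nb <- 0L
  for (s in 1:3) {
    d <- dim(heads[[s]])
    ag <- model$spec$anchors[[s]] / model$strides[s]
    matches_all[[s]] <- build_targets_scale(labels, ag, d[2], d[3],
                                            cfg$anchor_t)
    nb <- nb + length(matches_all[[s]])
  }
  dheads <- vector("list", 3)
  for (s in 1:3) {
    h <- heads[[s]]
    d <- dim(h)
    Hg <- d[2]; Wg <- d[3]
    arr <- array(h, c(no, 3L, Hg, Wg))
    darr <- array(0, c(no, 3L, Hg, Wg))
    tobj <- array(0, c(3L, Hg, Wg))
    ag <- model$spec$anchors[[s]] / model$strides[s]
    for (m in matches_all[[s]]) {
      a <- m[["a"]]; gi <- m[["gi"]]; gj <- m[["gj"]]
      gt <- c(m[["gx"]] - m[["gw"]] / 2, m[["gy"]] - m[["gh"]] / 2,
              m[["gx"]] + m[["gw"]] / 2, m[["gy"]] + m[["gh"]] / 2)
      t4 <- arr[1:4, a, gj + 1, gi + 1]
      f <- function(t) -ciou(decode_box_grid(t, gi, gj, ag[a, ]), gt)
      ci <- -f(t4)
      lbox <- lbox + (1 - ci)
      g4 <- vapply(1:4, function(k) {
        tp <- t4; tp[k] <- tp[k] + eps_fd
        tm <- t4; tm[k] <- tm[k] - eps_fd
        (f(tp) - f(tm)) / (2 * eps_fd)
      }, numeric(1))
      darr[1:4, a, gj + 1, gi + 1] <- darr[1:4, a, gj + 1, gi + 1] +
        cfg$box_gain * g4 / max(nb, 1)
      tobj[a, gj + 1, gi + 1] <- max(tobj[a, gj + 1, gi + 1], max(ci, 0))
      if (nc > 0) {
        tc <- arr[5L + seq_len(nc), a, gj + 1, gi + 1]
        y <- numeric(nc); y[m[["cl"]] + 1] <- 1
        lcls <- lcls + mean(bce_logit(tc, y))
        darr[5L + seq_len(nc), a, gj + 1, gi + 1] <-
          darr[5L + seq_len(nc), a, gj + 1, gi + 1] +
          cfg$cls_gain * (sigmoid_arr(tc) - y) / (nc * max(nb, 1))
      }
    }
    to <- arr[5, , , , drop = FALSE]
    po <- sigmoid_arr(to)
    n_cells <- length(tobj)
    lobj <- lobj + cfg$balance[s] * mean(bce_logit(as.vector(to),
                                                   as.vector(tobj)))
    darr[5, , , ] <- darr[5, , , ] +
      cfg$obj_gain * cfg$balance[s] *
        (array(po, dim(tobj)) - tobj) / n_cells
    dheads[[s]] <- array(darr, d)
  }
  comp <- c(box = cfg$box_gain * lbox / max(nb, 1),
            obj = cfg$obj_gain * lobj,
            cls = cfg$cls_gain * lcls / max(nb, 1))
  list(loss = sum(comp), components = comp, dheads = dheads, n_assigned = nb)
}
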