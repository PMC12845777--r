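# The composite detection loss: assignment, exact zero of the box term on a
# perfect prediction, degenerate inputs and label validation.

tiny_model <- function(nc = 1L)
  build_model(model_spec(nc = nc, width_multiple = 0.125, input_size = 64L))

# Raw heads for a model at a given input size, all logits at a constant.
flat_heads <- function(model, size, value = -6) {
  no <- 3L * (model$spec$nc + 5L)
  lapply(model$strides, function(s)
    array(value, c(no, size / s, size / s)))
}

test_that("a perfect prediction has a zero box term", {
  m <- tiny_model(nc = 1L)
  size <- 64L
  cfg <- train_config(epochs = 1, early_stop_patience = 1, image_size = size)
  # truth centred in a cell of the stride-8 grid, sized exactly like anchor 1
  stride <- 8; anchor <- m$spec$anchors[[1]][1, ]       # (10, 13) px
  cx <- (2 + 0.5) * stride / size; cy <- (3 + 0.5) * stride / size
  labels <- validate_labels(matrix(c(0, cx, cy, anchor[1] / size,
                                     anchor[2] / size), 1), nc = 1)
  heads <- flat_heads(m, size)
  # solve the decode equations exactly at every assigned (anchor, cell) slot
  no <- m$spec$nc + 5L
  for (s in 1:3) {
    g <- size / m$strides[s]
    ag <- m$spec$anchors[[s]] / m$strides[s]
    ms <- gefay:::build_targets_scale(labels, ag, g, g, cfg$anchor_t)
    if (!length(ms)) next
    arr <- array(heads[[s]], c(no, 3, g, g))
    for (mm in ms) {
      a <- mm["a"]
      arr[1, a, mm["gj"] + 1, mm["gi"] + 1] <-
        stats::qlogis((mm["gx"] - mm["gi"] + 0.5) / 2)
      arr[2, a, mm["gj"] + 1, mm["gi"] + 1] <-
        stats::qlogis((mm["gy"] - mm["gj"] + 0.5) / 2)
      arr[3, a, mm["gj"] + 1, mm["gi"] + 1] <-
        stats::qlogis(sqrt(mm["gw"] / ag[a, 1]) / 2)
      arr[4, a, mm["gj"] + 1, mm["gi"] + 1] <-
        stats::qlogis(sqrt(mm["gh"] / ag[a, 2]) / 2)
      arr[5, a, mm["gj"] + 1, mm["gi"] + 1] <- 6     # confident objectness
      arr[6, a, mm["gj"] + 1, mm["gi"] + 1] <- 6     # confident class
    }
    heads[[s]] <- array(arr, dim(heads[[s]]))
  }
  ls <- detection_loss(m, heads, labels, cfg)
  expect_gt(ls$n_assigned, 0)
  expect_equal(unname(ls$components["box"]), 0, tolerance = 1e-9)
  expect_true(is.finite(ls$loss))
})

test_that("an empty label set leaves only the objectness term", {
  m <- tiny_model()
  cfg <- train_config(epochs = 1, early_stop_patience = 1, image_size = 64L)
  ls <- detection_loss(m, flat_heads(m, 64L), validate_labels(NULL, 1), cfg)
  expect_equal(unname(ls$components["box"]), 0)
  expect_equal(unname(ls$components["cls"]), 0)
  expect_gt(unname(ls$components["obj"]), 0)
  expect_true(is.finite(ls$loss))
  # gradients exist only on the objectness channel
  no <- m$spec$nc + 5L
  for (s in 1:3) {
    darr <- array(ls$dheads[[s]], c(no, 3, dim(ls$dheads[[s]])[2],
                                    dim(ls$dheads[[s]])[3]))
    expect_true(all(darr[c(1:4, 6:no), , , ] == 0))
    expect_true(any(darr[5, , , ] != 0))
  }
})

test_that("assignment replicates matches into neighbouring cells", {
  m <- tiny_model()
  # an off-centre truth picks the base cell plus two neighbours
  ag <- m$spec$anchors[[1]] / 8
  ms <- gefay:::build_targets_scale(
    matrix(c(0, 0.30, 0.30, ag[1, 1] / 8, ag[1, 2] / 8), 1),
    ag, 8, 8, anchor_t = 4)
  cells <- unique(t(vapply(ms, function(m) c(m["gi"], m["gj"]), numeric(2))))
  expect_gte(nrow(cells), 2)
  # an anchor with a grossly mismatched shape is never assigned
  none <- gefay:::build_targets_scale(
    matrix(c(0, 0.5, 0.5, 0.001, 0.9), 1),
    matrix(1, 3, 2), 8, 8, anchor_t = 4)
  expect_length(none, 0)
})

test_that("malformed labels fail with the source position", {
  expect_error(validate_labels(matrix(c(0, 1.2, 0.5, 0.1, 0.1), 1), 3,
                               "lbl.txt"),
               "lbl.txt line 1")
  expect_error(validate_labels(matrix(c(5, 0.5, 0.5, 0.1, 0.1), 1), 3),
               "class id")
  expect_error(validate_labels(matrix(c(0.5, 0.5, 0.5, 0.1, 0.1), 1), 3),
               "class id")
})
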