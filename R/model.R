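# Detector assembly: Conv block, Bottleneck, C3, AttentionC3, SPPF, PANet
# neck and the three-scale anchor head, built from a declarative model_spec
# into one primitive graph.  The layout is the v6-generation small-detector
# graph: 6x6 stride-2 stem, CSP (C3) stages at base channels 128/256/512/1024
# scaled by width_multiple, SPPF at the backbone end, a two-up two-down PANet
# and 1x1 head convolutions emitting 3*(nc+5) channels per scale.

default_anchors <- function() list(
  p3 = matrix(c(10, 13, 16, 30, 33, 23), ncol = 2, byrow = TRUE),
  p4 = matrix(c(30, 61, 62, 45, 59, 119), ncol = 2, byrow = TRUE),
  p5 = matrix(c(116, 90, 156, 198, 373, 326), ncol = 2, byrow = TRUE))

#' Detector model specification
#'
#' @param nc number of object classes.
#' @param depth_multiple multiplier on the base repeat counts of the C3
#'   stages (small variant: 0.33).
#' @param width_multiple multiplier on the base channel widths; scaled widths
#'   are rounded to the nearest multiple of 8.
#' @param input_size nominal square input size (must be divisible by 32).
#' @param anchors list of three 3x2 matrices of anchor (w, h) pixel pairs for
#'   strides 8/16/32.
#' @param attention an [attention_spec()]; `variant = "none"` gives the plain
#'   baseline.
#' @param attention_placement character subset of the named C3 slots
#'   `c("P2","P3","P4","P5","N1","N2","N3","N4")` where the attention module
#'   is inserted after the C3 output.
#' @export
model_spec <- function(nc = 80L, depth_multiple = 0.33, width_multiple = 0.50,
                       input_size = 640L, anchors = default_anchors(),
                       attention = attention_spec("none"),
                       attention_placement = c("P2", "P3", "P4", "P5")) {
  stopifnot(nc >= 1, depth_multiple > 0, width_multiple > 0,
            input_size %% 32 == 0, length(anchors) == 3,
            inherits(attention, "attention_spec"))
  slots <- c("P2", "P3", "P4", "P5", "N1", "N2", "N3", "N4")
  bad <- setdiff(attention_placement, slots)
  if (length(bad))
    stop("unknown attention placement slot(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(nc = as.integer(nc), depth_multiple = depth_multiple,
                 width_multiple = width_multiple,
                 input_size = as.integer(input_size), anchors = anchors,
                 attention = attention,
                 attention_placement = attention_placement),
            class = "model_spec")
}

scale_ch <- function(c_base, width) {
  v <- max(8L, 8L * round_half_up(c_base * width / 8))
  as.integer(v)
}

scale_depth <- function(n_base, depth) max(1L, round_half_up(n_base * depth))

## ---- block emitters -----------------------------------------------------

emit_conv <- function(gr, from, cin, cout, k, s, block, pad = k %/% 2L) {
  if (cin < 1 || cout < 1 || k < 1 || s < 1)
    stop("invalid convolution block dimensions", call. = FALSE)
  c1 <- graph_add(gr, "conv", from,
                  list(k = as.integer(k), s = as.integer(s),
                       pad = as.integer(pad), g = 1L, cin = as.integer(cin),
                       cout = as.integer(cout), bias = FALSE), block)
  b1 <- graph_add(gr, "bn", c1, list(c = cout, eps = 1e-5, momentum = 0.1),
                  block)
  graph_add(gr, "silu", b1, block = block)
}

emit_bottleneck <- function(gr, from, c, shortcut, block) {
  y1 <- emit_conv(gr, from, c, c, 1L, 1L, block)
  y2 <- emit_conv(gr, y1, c, c, 3L, 1L, block)
  if (shortcut) graph_add(gr, "add", c(y2, from), block = block) else y2
}

emit_c3 <- function(gr, from, cin, cout, n, shortcut, block) {
  if (cout %% 2L != 0L)
    stop("C3 output channels must be even, got ", cout, call. = FALSE)
  ch <- cout %/% 2L
  a <- emit_conv(gr, from, cin, ch, 1L, 1L, block)
  for (i in seq_len(n)) a <- emit_bottleneck(gr, a, ch, shortcut, block)
  b <- emit_conv(gr, from, cin, ch, 1L, 1L, block)
  cc <- graph_add(gr, "concat", c(a, b), block = block)
  emit_conv(gr, cc, 2L * ch, cout, 1L, 1L, block)
}

emit_sppf <- function(gr, from, cin, cout, k, block) {
  ch <- cin %/% 2L
  a <- emit_conv(gr, from, cin, ch, 1L, 1L, block)
  mp <- list(k = as.integer(k), s = 1L, pad = as.integer(k %/% 2L))
  m1 <- graph_add(gr, "maxpool", a, mp, block)
  m2 <- graph_add(gr, "maxpool", m1, mp, block)
  m3 <- graph_add(gr, "maxpool", m2, mp, block)
  cc <- graph_add(gr, "concat", c(a, m1, m2, m3), block = block)
  emit_conv(gr, cc, 4L * ch, cout, 1L, 1L, block)
}

## ---- standalone blocks (hand-countable units) ---------------------------

standalone <- function(emitter) {
  gr <- graph_new()
  out <- emitter(gr)
  model <- list(nodes = gr$nodes, out_ids = out, roles = gr$roles)
  model$state <- init_state(model)
  model
}

#' Build a standalone Conv block (conv + norm + SiLU)
#'
#' Parameter count is `k^2 * c_in * c_out + 2 * c_out` (bias-free convolution
#' plus the affine normalisation weights).
#'
#' @param c_in,c_out channel counts; `k` kernel; `s` stride.
#' @param seed weight-initialisation seed.
#' @return a `gefay_block` with `$n_params` and `$apply(x)`.
#' @export
build_conv_block <- function(c_in, c_out, k = 1L, s = 1L, seed = 0L) {
  m <- standalone(function(gr) emit_conv(gr, 0L, c_in, c_out, k, s, 1L))
  finish_block(m, seed)
}

#' Build a standalone C3 block
#'
#' Two half-width 1x1 entry branches, `n` bottlenecks (1x1 then 3x3 with a
#' residual when `shortcut`), concatenation and a 1x1 exit fusion.
#'
#' @param c_in,c_out channel counts (`c_out` must be even).
#' @param n number of bottleneck repeats (already depth-scaled).
#' @param shortcut residual connections inside the bottlenecks.
#' @param seed weight-initialisation seed.
#' @export
build_c3 <- function(c_in, c_out, n = 1L, shortcut = TRUE, seed = 0L) {
  m <- standalone(function(gr) emit_c3(gr, 0L, c_in, c_out, n, shortcut, 1L))
  finish_block(m, seed)
}

#' Build a standalone AttentionC3 block
#'
#' A C3 block whose output passes through the attention plug-in named by
#' `spec`; `variant = "none"` degenerates to the plain C3 exactly.
#'
#' @inheritParams build_c3
#' @param spec an [attention_spec()].
#' @export
build_attention_c3 <- function(c_in, c_out, n = 1L, spec = attention_spec("none"),
                               shortcut = TRUE, seed = 0L) {
  m <- standalone(function(gr) {
    y <- emit_c3(gr, 0L, c_in, c_out, n, shortcut, 1L)
    attach_attention(gr, y, c_out, spec, 1L)
  })
  finish_block(m, seed)
}

finish_block <- function(model, seed) {
  model$params <- init_params(model, seed)
  model$n_params <- sum(lengths_params(model$params))
  model$apply <- function(x, train = FALSE)
    forward_graph(model, model$params, x, train = train)$heads[[1]]
  class(model) <- "gefay_block"
  model
}

## ---- full detector ------------------------------------------------------

#' Build the detector graph from a model specification
#'
#' Assembles stem, CSP backbone, SPPF, PANet neck and three-scale head, with
#' the attention module of `spec$attention` inserted at the C3 slots named in
#' `spec$attention_placement`.
#'
#' @param spec a [model_spec()].
#' @param seed weight-initialisation seed.
#' @return a `gefay_model`; inspect `$records` for the per-layer table.
#' @export
build_model <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "model_spec"))
  w <- spec$width_multiple
  ch <- vapply(c(64, 128, 256, 512, 1024), scale_ch, integer(1), width = w)
  names(ch) <- c("c64", "c128", "c256", "c512", "c1024")
  d3 <- scale_depth(3L, spec$depth_multiple)
  d6 <- scale_depth(6L, spec$depth_multiple)
  d9 <- scale_depth(9L, spec$depth_multiple)

  gr <- graph_new()
  rec <- list()
  blk <- 0L
  sz <- spec$input_size
  note <- function(name, kind, cin, cout, k, s, n, size) {
    rec[[length(rec) + 1L]] <<- data.frame(
      name = name, kind = kind, in_channels = cin, out_channels = cout,
      kernel = k, stride = s, repeats = n, out_size = size,
      stringsAsFactors = FALSE)
  }
  nb <- function() { blk <<- blk + 1L; blk }

  slot_out <- list()
  attn_here <- function(name) name %in% spec$attention_placement &&
    spec$attention$variant != "none"
  place_c3 <- function(from, cin, cout, n, shortcut, name, size) {
    b <- nb()
    y <- emit_c3(gr, from, cin, cout, n, shortcut, b)
    kind <- "c3"
    if (attn_here(name)) {
      y <- attach_attention(gr, y, cout, spec$attention, b)
      kind <- "attnc3"
    }
    note(name, kind, cin, cout, 1L, 1L, n, size)
    slot_out[[name]] <<- y
    y
  }

  # backbone
  y <- emit_conv(gr, 0L, 3L, ch["c64"], 6L, 2L, nb(), pad = 2L)
  sz <- sz / 2; note("stem", "conv", 3L, ch["c64"], 6L, 2L, 1L, sz)
  y <- emit_conv(gr, y, ch["c64"], ch["c128"], 3L, 2L, nb())
  sz <- sz / 2; note("down_p2", "conv", ch["c64"], ch["c128"], 3L, 2L, 1L, sz)
  y <- place_c3(y, ch["c128"], ch["c128"], d3, TRUE, "P2", sz)
  y <- emit_conv(gr, y, ch["c128"], ch["c256"], 3L, 2L, nb())
  sz <- sz / 2; note("down_p3", "conv", ch["c128"], ch["c256"], 3L, 2L, 1L, sz)
  p3 <- place_c3(y, ch["c256"], ch["c256"], d6, TRUE, "P3", sz); sz3 <- sz
  y <- emit_conv(gr, p3, ch["c256"], ch["c512"], 3L, 2L, nb())
  sz <- sz / 2; note("down_p4", "conv", ch["c256"], ch["c512"], 3L, 2L, 1L, sz)
  p4 <- place_c3(y, ch["c512"], ch["c512"], d9, TRUE, "P4", sz); sz4 <- sz
  y <- emit_conv(gr, p4, ch["c512"], ch["c1024"], 3L, 2L, nb())
  sz <- sz / 2; note("down_p5", "conv", ch["c512"], ch["c1024"], 3L, 2L, 1L, sz)
  y <- place_c3(y, ch["c1024"], ch["c1024"], d3, TRUE, "P5", sz)
  y <- emit_sppf(gr, y, ch["c1024"], ch["c1024"], 5L, nb())
  note("sppf", "sppf", ch["c1024"], ch["c1024"], 5L, 1L, 1L, sz)

  # neck: top-down
  lat5 <- emit_conv(gr, y, ch["c1024"], ch["c512"], 1L, 1L, nb())
  note("lat_p5", "conv", ch["c1024"], ch["c512"], 1L, 1L, 1L, sz)
  u1 <- graph_add(gr, "up2", lat5, block = nb())
  note("up_p4", "upsample", ch["c512"], ch["c512"], 0L, 0L, 1L, sz4)
  cc1 <- graph_add(gr, "concat", c(u1, p4), block = nb())
  note("cat_p4", "concat", 2L * ch["c512"], 2L * ch["c512"], 0L, 0L, 1L, sz4)
  n1 <- place_c3(cc1, 2L * ch["c512"], ch["c512"], d3, FALSE, "N1", sz4)
  lat4 <- emit_conv(gr, n1, ch["c512"], ch["c256"], 1L, 1L, nb())
  note("lat_p4", "conv", ch["c512"], ch["c256"], 1L, 1L, 1L, sz4)
  u2 <- graph_add(gr, "up2", lat4, block = nb())
  note("up_p3", "upsample", ch["c256"], ch["c256"], 0L, 0L, 1L, sz3)
  cc2 <- graph_add(gr, "concat", c(u2, p3), block = nb())
  note("cat_p3", "concat", 2L * ch["c256"], 2L * ch["c256"], 0L, 0L, 1L, sz3)
  o3 <- place_c3(cc2, 2L * ch["c256"], ch["c256"], d3, FALSE, "N2", sz3)
  # bottom-up
  dn1 <- emit_conv(gr, o3, ch["c256"], ch["c256"], 3L, 2L, nb())
  note("down_n3", "conv", ch["c256"], ch["c256"], 3L, 2L, 1L, sz4)
  cc3 <- graph_add(gr, "concat", c(dn1, lat4), block = nb())
  note("cat_n3", "concat", 2L * ch["c256"], 2L * ch["c256"], 0L, 0L, 1L, sz4)
  o4 <- place_c3(cc3, 2L * ch["c256"], ch["c512"], d3, FALSE, "N3", sz4)
  dn2 <- emit_conv(gr, o4, ch["c512"], ch["c512"], 3L, 2L, nb())
  note("down_n4", "conv", ch["c512"], ch["c512"], 3L, 2L, 1L, sz)
  cc4 <- graph_add(gr, "concat", c(dn2, lat5), block = nb())
  note("cat_n4", "concat", 2L * ch["c512"], 2L * ch["c512"], 0L, 0L, 1L, sz)
  o5 <- place_c3(cc4, 2L * ch["c512"], ch["c1024"], d3, FALSE, "N4", sz)

  # head
  no <- 3L * (spec$nc + 5L)
  hin <- unname(c(ch["c256"], ch["c512"], ch["c1024"]))
  hsrc <- c(o3, o4, o5)
  hsz <- c(sz3, sz4, sz)
  out_ids <- integer(3)
  for (s in 1:3) {
    b <- nb()
    out_ids[s] <- graph_add(gr, "conv", hsrc[s],
                            list(k = 1L, s = 1L, pad = 0L, g = 1L,
                                 cin = hin[s], cout = no, bias = TRUE), b)
    note(paste0("head_p", s + 2L), "head", hin[s], no, 1L, 1L, 1L, hsz[s])
  }

  records <- do.call(rbind, rec)
  model <- list(spec = spec, nodes = gr$nodes, out_ids = out_ids,
                roles = gr$roles, records = records,
                strides = c(8L, 16L, 32L), channels = ch)
  model$state <- init_state(model)
  model$params <- init_params(model, seed)
  model$params <- init_head_biases(model, model$params)
  class(model) <- "gefay_model"
  model
}

# objectness/class prior initialisation of the head biases: start the
# objectness logit near the expected object density per cell and the class
# logits near uniform low probability, which stabilises early training.
init_head_biases <- function(model, params) {
  nc <- model$spec$nc
  no <- nc + 5L
  for (s in 1:3) {
    id <- model$out_ids[s]
    stride <- model$strides[s]
    b <- params[[id]]$b
    for (a in 0:2) {
      b[a * no + 5L] <- log(8 / (model$spec$input_size / stride)^2)
      if (nc > 1)
        b[a * no + 5L + seq_len(nc)] <- log(0.6 / (nc - 0.99))
    }
    params[[id]]$b <- b
  }
  params
}

#' Run the detector forward
#'
#' @param model a `gefay_model`.
#' @param x a feature-map array `c(3, H, W)` with `H`, `W` divisible by 32,
#'   or a list of such arrays (the batch axis).
#' @param train use batch statistics in normalisation layers.
#' @return for a single image, a list of three raw head arrays (one per
#'   stride 8/16/32), each `c(3*(nc+5), H/s, W/s)`; for a list input, a list
#'   of such lists.
#' @export
model_forward <- function(model, x, train = FALSE) {
  if (is.list(x)) return(lapply(x, function(xi) model_forward(model, xi, train)))
  d <- fmap_dims(x)
  if (d[2] %% 32 != 0 || d[3] %% 32 != 0)
    stop("input spatial size must be divisible by 32", call. = FALSE)
  forward_graph(model, model$params, x, train = train)$heads
}

#' @export
print.gefay_model <- function(x, ...) {
  cat(sprintf("<gefay_model> nc=%d depth=%.2f width=%.2f attention=%s\n",
              x$spec$nc, x$spec$depth_multiple, x$spec$width_multiple,
              x$spec$attention$variant))
  cat(sprintf("  %d macro layers, %d graph nodes, %s parameters\n",
              nrow(x$records), length(x$nodes),
              format(sum(lengths_params(x$params)), big.mark = ",")))
  invisible(x)
}

#' Export the per-layer record table
#'
#' @param model a `gefay_model`.
#' @param path optional TSV destination; when `NULL` the data.frame is
#'   returned invisibly only.
#' @export
layer_records <- function(model, path = NULL) {
  df <- model$records
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  df
}
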