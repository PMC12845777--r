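# Primitive tensor operations on feature maps stored as arrays with
# dim c(C, H, W).  Channel-first layout means per-channel scalars recycle
# naturally in R's column-major arithmetic: `x - m` subtracts m[c] from every
# element of channel c when length(m) == C.
#
# Each op has a forward returning list(y, cache) and a backward returning
# gradients w.r.t. inputs and parameters.  Only convolution and max pooling
# go through compiled code.

fmap_dims <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L)
    stop("feature map must be an array with dim c(C, H, W)", call. = FALSE)
  d
}

#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

sigmoid_arr <- function(x) 1 / (1 + exp(-x))

## ---- elementwise activations -------------------------------------------

op_silu_fw <- function(x) {
  s <- sigmoid_arr(x)
  list(y = x * s, cache = list(x = x, s = s))
}
op_silu_bw <- function(cache, dy) dy * (cache$s * (1 + cache$x * (1 - cache$s)))

op_relu_fw <- function(x) {
  y <- x
  y[y < 0] <- 0
  list(y = y, cache = list(mask = x > 0))
}
op_relu_bw <- function(cache, dy) dy * cache$mask

op_sigmoid_fw <- function(x) {
  y <- sigmoid_arr(x)
  list(y = y, cache = list(y = y))
}
op_sigmoid_bw <- function(cache, dy) dy * cache$y * (1 - cache$y)

## ---- normalization ------------------------------------------------------

bn_fw <- function(x, gamma, beta, rm, rv, eps, momentum, train) {
  d <- fmap_dims(x)
  C <- d[1]
  if (train) {
    xm <- matrix(x, nrow = C)
    m <- rowMeans(xm)
    v <- rowMeans(xm * xm) - m * m
    v[v < 0] <- 0
    rm_new <- (1 - momentum) * rm + momentum * m
    rv_new <- (1 - momentum) * rv + momentum * v
  } else {
    m <- rm; v <- rv; rm_new <- rm; rv_new <- rv
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (x - m) * inv
  list(y = gamma * xhat + beta,
       cache = list(xhat = xhat, inv = inv, gamma = gamma),
       rm = rm_new, rv = rv_new)
}

bn_bw <- function(cache, dy) {
  xhat <- cache$xhat
  C <- dim(xhat)[1]
  n <- length(xhat) / C
  dym <- matrix(dy, nrow = C)
  dgamma <- rowSums(dym * matrix(xhat, nrow = C))
  dbeta <- rowSums(dym)
  g <- cache$gamma * cache$inv
  # dx = g * (dy - mean(dy) - xhat * mean(dy * xhat)) per channel
  dx <- g * (dy - dbeta / n - xhat * (dgamma / n))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- pooling / resampling ----------------------------------------------

#' Local average pooling of a feature map onto a p x p grid
#'
#' Partitions the spatial extent into an adaptive `p` x `p` grid (region
#' boundaries at `floor(i * H / p)`) and averages within each region,
#' producing one descriptor per region and channel.
#'
#' @param x numeric array with dim `c(C, H, W)`.
#' @param p grid size (positive integer).
#' @return numeric array with dim `c(C, p, p)` of region means.
#' @export
local_avg_pool <- function(x, p) {
  d <- fmap_dims(x)
  C <- d[1]; H <- d[2]; W <- d[3]
  p <- as.integer(p)
  if (p < 1) stop("p must be >= 1", call. = FALSE)
  if (H < p || W < p) stop("spatial size smaller than pooling grid", call. = FALSE)
  bh <- floor((0:p) * H / p); bw <- floor((0:p) * W / p)
  y <- array(0, c(C, p, p))
  for (j in seq_len(p)) for (i in seq_len(p)) {
    rs <- (bh[i] + 1):bh[i + 1]; cs <- (bw[j] + 1):bw[j + 1]
    y[, i, j] <- rowMeans(matrix(x[, rs, cs, drop = FALSE], nrow = C))
  }
  y
}

lap_bw <- function(dy, C, H, W, p) {
  bh <- floor((0:p) * H / p); bw <- floor((0:p) * W / p)
  dx <- array(0, c(C, H, W))
  for (j in seq_len(p)) for (i in seq_len(p)) {
    rs <- (bh[i] + 1):bh[i + 1]; cs <- (bw[j] + 1):bw[j + 1]
    dx[, rs, cs] <- dy[, i, j] / (length(rs) * length(cs))
  }
  dx
}

#' Nearest-neighbour de-pooling of grid weights back to full resolution
#'
#' Expands a `C` x `p` x `p` grid of region weights to `C` x `H` x `W` by
#' assigning every pixel the value of the region it falls in (the inverse
#' partition of [local_avg_pool()]).
#'
#' @param w numeric array with dim `c(C, p, p)`.
#' @param H,W target spatial size; both must be `>= p`.
#' @return numeric array with dim `c(C, H, W)`.
#' @export
local_unpool <- function(w, H, W) {
  d <- fmap_dims(w)
  p <- d[2]
  if (d[3] != p) stop("weight grid must be square", call. = FALSE)
  if (p > H || p > W) stop("target size smaller than grid", call. = FALSE)
  bh <- floor((0:p) * H / p); bw <- floor((0:p) * W / p)
  ih <- rep(seq_len(p), times = diff(bh))
  iw <- rep(seq_len(p), times = diff(bw))
  w[, ih, iw, drop = FALSE]
}

unpool_bw <- function(dy, p) {
  d <- dim(dy)
  C <- d[1]; H <- d[2]; W <- d[3]
  bh <- floor((0:p) * H / p); bw <- floor((0:p) * W / p)
  dw <- array(0, c(C, p, p))
  for (j in seq_len(p)) for (i in seq_len(p)) {
    rs <- (bh[i] + 1):bh[i + 1]; cs <- (bw[j] + 1):bw[j + 1]
    dw[, i, j] <- rowSums(matrix(dy[, rs, cs, drop = FALSE], nrow = C))
  }
  dw
}

up2_fw <- function(x) {
  d <- fmap_dims(x)
  x[, rep(seq_len(d[2]), each = 2), rep(seq_len(d[3]), each = 2), drop = FALSE]
}

up2_bw <- function(dy) {
  d <- dim(dy)
  H <- d[2] / 2; W <- d[3] / 2
  oh <- seq(1, d[2], by = 2); ow <- seq(1, d[3], by = 2)
  dy[, oh, ow, drop = FALSE] + dy[, oh + 1, ow, drop = FALSE] +
    dy[, oh, ow + 1, drop = FALSE] + dy[, oh + 1, ow + 1, drop = FALSE]
}

gap_fw <- function(x) {
  C <- dim(x)[1]
  array(rowMeans(matrix(x, nrow = C)), c(C, 1, 1))
}

## ---- 1-D channel mixer --------------------------------------------------

#' Mix channel descriptors with a shared 1-D convolution
#'
#' Applies a single learned filter of odd length `k` along the channel axis,
#' zero-padded, shared across the `m` positional descriptors.  This is the
#' local cross-channel interaction used by ECA-style attention: each channel
#' attends to its `k` nearest channels only, so the mixer carries exactly
#' `k` weights regardless of `C` and `m`.
#'
#' @param desc numeric matrix or array reshaped to `C` x `m`.
#' @param w numeric filter of odd length `k`.
#' @return array of the same shape as `desc`.
#' @export
channel_mix_1d <- function(desc, w) {
  k <- length(w)
  if (k %% 2 == 0) stop("channel mixer kernel must be odd", call. = FALSE)
  d <- dim(desc)
  C <- d[1]
  x <- matrix(desc, nrow = C)
  y <- matrix(0, nrow = C, ncol = ncol(x))
  h <- (k - 1) / 2
  for (o in -h:h) {
    src <- seq_len(C) + o
    ok <- src >= 1 & src <= C
    y[ok, ] <- y[ok, , drop = FALSE] + w[o + h + 1] * x[src[ok], , drop = FALSE]
  }
  array(y, d)
}

chanmix_bw <- function(desc, w, dy) {
  k <- length(w); h <- (k - 1) / 2
  d <- dim(desc)
  C <- d[1]
  x <- matrix(desc, nrow = C)
  g <- matrix(dy, nrow = C)
  dx <- matrix(0, nrow = C, ncol = ncol(x))
  dw <- numeric(k)
  for (o in -h:h) {
    src <- seq_len(C) + o
    ok <- src >= 1 & src <= C
    dw[o + h + 1] <- sum(g[ok, , drop = FALSE] * x[src[ok], , drop = FALSE])
    dx[src[ok], ] <- dx[src[ok], , drop = FALSE] + w[o + h + 1] * g[ok, , drop = FALSE]
  }
  list(dx = array(dx, d), dw = dw)
}

## ---- combination ops ----------------------------------------------------

broadcast_to <- function(b, d) {
  db <- dim(b)
  if (all(db == d)) return(b)
  if (db[1] == d[1] && db[2] == 1L && db[3] == 1L)
    return(array(as.vector(b), d))  # recycles channel-wise
  stop("incompatible shapes for broadcast", call. = FALSE)
}

# reduce a full-size gradient back onto a (C,1,1) operand if it was broadcast
reduce_like <- function(g, d_operand) {
  if (all(dim(g) == d_operand)) return(g)
  array(rowSums(matrix(g, nrow = d_operand[1])), d_operand)
}

concat_fw <- function(ins) {
  d1 <- dim(ins[[1]])
  Cs <- vapply(ins, function(z) dim(z)[1], integer(1))
  y <- array(0, c(sum(Cs), d1[2], d1[3]))
  at <- 0L
  for (z in ins) {
    C <- dim(z)[1]
    y[at + seq_len(C), , ] <- z
    at <- at + C
  }
  list(y = y, Cs = Cs)
}
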