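# The attention zoo: GEFA (group-enhanced fusion attention) plus the
# comparison operators SE, ECA, CA, CBAM and MLCA, all behind one plug-in
# interface so any of them can fill the attention slot of an AttentionC3
# block.  GEFA, SE, ECA and MLCA are expressed in graph primitives and are
# fully trainable; CA and CBAM are forward/profiling modules (they are
# comparison points, not part of the trained detector).

#' Adaptive 1-D kernel size from the channel count
#'
#' Chooses the channel-mixer kernel `k` from the channel count `C` as
#' `k = round(log2(C)/gamma + b/gamma)` (round half up), incremented by one
#' if even, and clamped below at `min_k`, so each channel interacts with its
#' `k` nearest channels only.
#'
#' @param C channel count, a positive integer.
#' @param policy list with `gamma`, `b`, `min_k` (see [eca_policy()]).
#' @return an odd integer kernel size.
#' @examples
#' eca_kernel_size(256)  # 5
#' @export
eca_kernel_size <- function(C, policy = eca_policy()) {
  if (length(C) != 1 || !is.finite(C) || C < 1)
    stop("C must be a positive integer", call. = FALSE)
  k <- floor(log2(C) / policy$gamma + policy$b / policy$gamma + 0.5)
  if (k %% 2 == 0) k <- k + 1
  max(k, policy$min_k)
}

#' Kernel-size policy for adaptive channel mixing
#'
#' @param gamma,b positive reals controlling how fast the kernel grows with
#'   `log2(C)`; both default to 2.
#' @param min_k smallest admissible (odd) kernel.
#' @export
eca_policy <- function(gamma = 2, b = 2, min_k = 3L) {
  stopifnot(gamma > 0, b > 0, min_k >= 1, min_k %% 2 == 1)
  list(gamma = gamma, b = b, min_k = as.integer(min_k))
}

round_half_up <- function(x) floor(x + 0.5)

#' Attention variant specification
#'
#' Collects the hyperparameters of every supported attention variant in one
#' validated object.  Fields irrelevant to a variant are ignored by it.
#'
#' @param variant one of `"none"`, `"se"`, `"eca"`, `"ca"`, `"cbam"`,
#'   `"mlca"`, `"gefa"`.
#' @param groups number of channel groups `G` (gefa). Every channel count the
#'   operator is applied to must be divisible by `G`.
#' @param local_grid local pooling grid `p` (mlca / gefa).
#' @param reduction dimension-reduction factor `r` (se / ca / cbam).
#' @param kernel_policy an [eca_policy()] for the adaptive 1-D mixer.
#' @param group_kernel spatial kernel of the grouped enhancement convolution
#'   (gefa; odd).
#' @param group_width_factor per-group hidden-width multiplier of the grouped
#'   enhancement bottleneck (gefa). The defaults for `groups`,
#'   `group_kernel` and `group_width_factor` are the configuration selected
#'   by [calibrate_gefa()].
#' @param share_mixer share the 1-D channel mixer between the local and
#'   global descriptor branches (gefa / mlca).
#' @export
attention_spec <- function(variant = "gefa", groups = 32L, local_grid = 5L,
                           reduction = NULL, kernel_policy = eca_policy(),
                           group_kernel = 3L, group_width_factor = 2.875,
                           share_mixer = TRUE) {
  variants <- c("none", "se", "eca", "ca", "cbam", "mlca", "gefa")
  if (!is.character(variant) || length(variant) != 1 || !variant %in% variants)
    stop("unknown attention variant: ", variant, call. = FALSE)
  if (is.null(reduction))
    reduction <- switch(variant, se = 4L, ca = 16L, cbam = 16L, 16L)
  stopifnot(groups >= 1, local_grid >= 1, reduction >= 1,
            group_kernel %% 2 == 1, group_width_factor > 0)
  structure(list(variant = variant, groups = as.integer(groups),
                 local_grid = as.integer(local_grid),
                 reduction = as.integer(reduction),
                 kernel_policy = kernel_policy,
                 group_kernel = as.integer(group_kernel),
                 group_width_factor = group_width_factor,
                 share_mixer = isTRUE(share_mixer)),
            class = "attention_spec")
}

gefa_hidden_per_group <- function(C, spec) {
  max(1L, round_half_up(spec$group_width_factor * C / spec$groups))
}

#' Closed-form learned-weight count of an attention insertion
#'
#' @param spec an [attention_spec()].
#' @param C channel count at the insertion point.
#' @return integer number of learned weights.
#' @export
attention_param_count <- function(spec, C) {
  kE <- eca_kernel_size(C, spec$kernel_policy)
  mix <- if (spec$share_mixer) kE else 2L * kE
  switch(spec$variant,
    none = 0L,
    se = {
      cr <- max(1L, ceiling(C / spec$reduction))
      2L * C * cr
    },
    eca = kE,
    ca = {
      mip <- max(8L, round_half_up(C / spec$reduction))
      3L * C * mip + 2L * mip
    },
    cbam = {
      h <- max(1L, round_half_up(C / spec$reduction))
      2L * C * h + 7L * 7L * 2L + 1L
    },
    mlca = mix,
    gefa = {
      G <- spec$groups
      if (C %% G != 0) stop("channels not divisible by groups", call. = FALSE)
      hg <- gefa_hidden_per_group(C, spec)
      Hh <- G * hg
      k <- spec$group_kernel
      as.integer(k * k * (C / G) * hg * G + 2L * Hh +
                 hg * (C / G) * G + 2L * C + mix)
    })
}

## ---- graph emission -----------------------------------------------------

# Appends the nodes of one attention insertion to graph `gr`, gating the
# output of node `from`.  Returns the id of the final node.
attach_attention <- function(gr, from, C, spec, block) {
  C <- as.integer(C)
  v <- spec$variant
  add <- function(op, f, attrs = list(), share = NA_integer_)
    graph_add(gr, op, f, attrs, block = block, share = share)
  if (v == "none") return(from)
  kE <- eca_kernel_size(C, spec$kernel_policy)
  if (v == "se") {
    cr <- max(1L, ceiling(C / spec$reduction))
    g1 <- add("gap", from)
    c1 <- add("conv", g1, list(k = 1L, s = 1L, pad = 0L, g = 1L, cin = C,
                               cout = cr, bias = FALSE))
    r1 <- add("relu", c1)
    c2 <- add("conv", r1, list(k = 1L, s = 1L, pad = 0L, g = 1L, cin = cr,
                               cout = C, bias = FALSE))
    s1 <- add("sigmoid", c2)
    return(add("mul", c(s1, from)))
  }
  if (v == "eca") {
    g1 <- add("gap", from)
    m1 <- add("chanmix", g1, list(k = kE))
    s1 <- add("sigmoid", m1)
    return(add("mul", c(s1, from)))
  }
  if (v == "mlca") {
    l1 <- add("lap", from, list(p = spec$local_grid))
    l2 <- add("chanmix", l1, list(k = kE))
    l3 <- add("unpool", c(l2, from))
    g1 <- add("gap", from)
    g2 <- if (spec$share_mixer) add("chanmix", g1, list(k = kE), share = l2)
          else add("chanmix", g1, list(k = kE))
    f1 <- add("mean2", c(l3, g2))
    s1 <- add("sigmoid", f1)
    return(add("mul", c(s1, from)))
  }
  if (v == "gefa") {
    G <- spec$groups
    if (C %% G != 0)
      stop("gefa: channel count ", C, " not divisible by groups ", G,
           call. = FALSE)
    hg <- gefa_hidden_per_group(C, spec)
    Hh <- as.integer(G * hg)
    gk <- spec$group_kernel
    c1 <- add("conv", from, list(k = gk, s = 1L, pad = (gk - 1L) %/% 2L,
                                 g = G, cin = C, cout = Hh, bias = FALSE))
    b1 <- add("bn", c1, list(c = Hh, eps = 1e-5, momentum = 0.1))
    a1 <- add("silu", b1)
    c2 <- add("conv", a1, list(k = 1L, s = 1L, pad = 0L, g = G, cin = Hh,
                               cout = C, bias = FALSE))
    U <- add("bn", c2, list(c = C, eps = 1e-5, momentum = 0.1))
    l1 <- add("lap", U, list(p = spec$local_grid))
    l2 <- add("chanmix", l1, list(k = kE))
    l3 <- add("unpool", c(l2, U))
    g1 <- add("gap", U)
    g2 <- if (spec$share_mixer) add("chanmix", g1, list(k = kE), share = l2)
          else add("chanmix", g1, list(k = kE))
    f1 <- add("mean2", c(l3, g2))
    A <- add("sigmoid", f1)
    m1 <- add("mul", c(A, U))
    y <- add("add", c(m1, from))
    gr$roles <- c(gr$roles, list(list(block = block, U = U, gate = A)))
    return(y)
  }
  # CA / CBAM: opaque forward-only modules
  fwd <- if (v == "ca") ca_forward_fn(C, spec) else cbam_forward_fn(C, spec)
  add("blackbox", from,
      list(variant = v, fwd = fwd$fwd, init = fwd$init))
}

## ---- forward-only comparison modules -----------------------------------

hard_swish <- function(x) {
  t <- x + 3
  t[t < 0] <- 0; t[t > 6] <- 6
  x * t / 6
}

ca_forward_fn <- function(C, spec) {
  mip <- max(8L, round_half_up(C / spec$reduction))
  init <- function() {
    b1 <- sqrt(6 / C); b2 <- sqrt(6 / mip)
    list(w1 = matrix(stats::runif(mip * C, -b1, b1), mip, C),
         gamma = rep(1, mip), beta = numeric(mip),
         wh = matrix(stats::runif(C * mip, -b2, b2), C, mip),
         ww = matrix(stats::runif(C * mip, -b2, b2), C, mip))
  }
  fwd <- function(x, par) {
    d <- dim(x); H <- d[2]; W <- d[3]
    ph <- sapply(seq_len(H), function(h) rowMeans(matrix(x[, h, , drop = FALSE], C)))
    pw <- sapply(seq_len(W), function(w) rowMeans(matrix(x[, , w, drop = FALSE], C)))
    desc <- par$w1 %*% cbind(ph, pw)                     # mip x (H+W)
    desc <- hard_swish(par$gamma * desc + par$beta)
    ah <- sigmoid_arr(par$wh %*% desc[, seq_len(H), drop = FALSE])   # C x H
    aw <- sigmoid_arr(par$ww %*% desc[, H + seq_len(W), drop = FALSE]) # C x W
    x * array(ah[, rep(seq_len(H), times = W)], d) *
        array(aw[, rep(seq_len(W), each = H)], d)
  }
  list(fwd = fwd, init = init)
}

cbam_forward_fn <- function(C, spec) {
  h <- max(1L, round_half_up(C / spec$reduction))
  init <- function() {
    b1 <- sqrt(6 / C); b2 <- sqrt(6 / h); b3 <- sqrt(6 / (49 * 2))
    list(w1 = matrix(stats::runif(h * C, -b1, b1), h, C),
         w2 = matrix(stats::runif(C * h, -b2, b2), C, h),
         ws = array(stats::runif(49 * 2, -b3, b3), c(7, 7, 2, 1)),
         bs = 0)
  }
  fwd <- function(x, par) {
    d <- dim(x)
    xm <- matrix(x, nrow = C)
    avg <- rowMeans(xm); mx <- apply(xm, 1, max)
    mlp <- function(v) par$w2 %*% pmax(par$w1 %*% v, 0)
    ac <- sigmoid_arr(mlp(avg) + mlp(mx))               # C x 1
    x1 <- x * as.vector(ac)
    smean <- colMeans(xm); smax <- apply(xm, 2, max)
    sdesc <- array(rbind(smean, smax), c(2, d[2], d[3]))
    as_ <- sigmoid_arr(cpp_conv2d_fw(sdesc, par$ws, par$bs, 1L, 3L, 1L))
    x1 * array(rep(as.vector(as_), each = C), d)
  }
  list(fwd = fwd, init = init)
}

## ---- plug-in contract ---------------------------------------------------

#' Construct a standalone attention module
#'
#' The plug-in contract consumed by AttentionC3: given a variant, a channel
#' count and an [attention_spec()], returns a module exposing a forward
#' application and a weight inventory.
#'
#' @param spec an [attention_spec()].
#' @param channels channel count `C` the module is built for.
#' @param seed integer seed for weight initialisation.
#' @return an object of class `attention_module`.
#' @export
construct_attention <- function(spec, channels, seed = 0L) {
  stopifnot(inherits(spec, "attention_spec"))
  gr <- graph_new()
  out <- attach_attention(gr, 0L, channels, spec, block = 1L)
  model <- list(nodes = gr$nodes, out_ids = out, roles = gr$roles)
  model$state <- init_state(model)
  params <- init_params(model, seed)
  structure(list(spec = spec, channels = channels, model = model,
                 params = params,
                 n_params = sum(lengths_params(params))),
            class = "attention_module")
}

lengths_params <- function(params)
  vapply(params,
         function(p) if (is.null(p)) 0L else sum(vapply(p, length, integer(1))),
         integer(1))

#' Apply an attention module to a feature map
#'
#' @param mod an `attention_module` from [construct_attention()].
#' @param x feature map array `c(C, H, W)`.
#' @param detail if `TRUE` and the variant is gefa, also return the enhanced
#'   features `U` and the gate `A` (so that `y = x + A * U`).
#' @param train use batch statistics in normalisation layers.
#' @export
attention_apply <- function(mod, x, detail = FALSE, train = FALSE) {
  d <- fmap_dims(x)
  if (d[1] != mod$channels)
    stop("module built for ", mod$channels, " channels, got ", d[1],
         call. = FALSE)
  if (mod$spec$variant == "none") return(x)
  fw <- forward_graph(mod$model, mod$params, x, train = train, keep = detail)
  y <- fw$heads[[1]]
  if (detail && mod$spec$variant == "gefa") {
    role <- mod$model$roles[[1]]
    return(list(y = y, U = fw$outs[[role$U]], gate = fw$outs[[role$gate]]))
  }
  y
}

#' @describeIn attention_apply convenience wrapper for the gefa variant.
#' @param spec an [attention_spec()] with `variant = "gefa"`.
#' @param seed seed for weight initialisation when `mod` is not supplied.
#' @export
gefa_apply <- function(x, spec = attention_spec("gefa"), mod = NULL,
                       detail = FALSE, seed = 0L) {
  if (is.null(mod)) mod <- construct_attention(spec, dim(x)[1], seed)
  attention_apply(mod, x, detail = detail)
}
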