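# A compiled model is a flat list of primitive nodes.  Node i holds
#   op    - primitive kind
#   from  - indices of producer nodes (0 = the network input)
#   attrs - static attributes (kernel, stride, channels, ...)
#   block - index of the macro layer (Conv, C3, SPPF, ...) it belongs to
#   share - for "chanmix": node id whose weights are reused (tied weights)
# Parameters live in a parallel list `params[[i]]`; batch-norm running
# statistics live in `state[[i]]`.  Forward and backward are two loops over
# this list, which keeps profiling, training and shape inference in one place.

graph_new <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$records <- list()
  env
}

graph_add <- function(gr, op, from, attrs = list(), block = NA_integer_,
                      share = NA_integer_) {
  i <- length(gr$nodes) + 1L
  gr$nodes[[i]] <- list(i = i, op = op, from = as.integer(from),
                        attrs = attrs, block = block, share = share)
  i
}

## ---- parameter initialisation ------------------------------------------

init_node_params <- function(node) {
  a <- node$attrs
  switch(node$op,
    conv = {
      cg <- a$cin / a$g
      fan_in <- a$k * a$k * cg
      bound <- sqrt(6 / fan_in)
      p <- list(w = array(stats::runif(a$k * a$k * cg * a$cout, -bound, bound),
                          c(a$k, a$k, cg, a$cout)))
      if (isTRUE(a$bias)) p$b <- numeric(a$cout)
      p
    },
    bn = list(gamma = rep(1, a$c), beta = numeric(a$c)),
    chanmix = if (is.na(node$share)) {
      bound <- 1 / sqrt(a$k)
      list(w = stats::runif(a$k, -bound, bound))
    } else NULL,
    blackbox = a$init(),
    NULL)
}

#' @keywords internal
init_params <- function(model, seed = 0L) {
  with_seed(seed, lapply(model$nodes, init_node_params))
}

init_state <- function(model) {
  lapply(model$nodes, function(node) {
    if (node$op == "bn")
      list(rm = numeric(node$attrs$c), rv = rep(1, node$attrs$c))
    else NULL
  })
}

## ---- forward ------------------------------------------------------------

forward_graph <- function(model, params, x, train = FALSE, state = NULL,
                          keep = FALSE) {
  fmap_dims(x)
  if (is.null(state)) state <- model$state
  n <- length(model$nodes)
  outs <- vector("list", n)
  caches <- if (keep) vector("list", n) else NULL
  for (i in seq_len(n)) {
    node <- model$nodes[[i]]
    a <- node$attrs
    ins <- lapply(node$from, function(f) if (f == 0L) x else outs[[f]])
    par <- params[[i]]
    r <- switch(node$op,
      conv = {
        y <- cpp_conv2d_fw(ins[[1]], par$w,
                           if (isTRUE(a$bias)) par$b else NULL,
                           a$s, a$pad, a$g)
        list(y = y, cache = ins[[1]])
      },
      bn = {
        st <- state[[i]]
        b <- bn_fw(ins[[1]], par$gamma, par$beta, st$rm, st$rv,
                   a$eps, a$momentum, train)
        state[[i]] <- list(rm = b$rm, rv = b$rv)
        list(y = b$y, cache = b$cache)
      },
      silu = op_silu_fw(ins[[1]]),
      relu = op_relu_fw(ins[[1]]),
      sigmoid = op_sigmoid_fw(ins[[1]]),
      add = list(y = ins[[1]] + ins[[2]], cache = NULL),
      mul = {
        d <- pmax(dim(ins[[1]]), dim(ins[[2]]))
        af <- broadcast_to(ins[[1]], d); bf <- broadcast_to(ins[[2]], d)
        list(y = af * bf, cache = list(a = ins[[1]], b = ins[[2]]))
      },
      mean2 = {
        d <- pmax(dim(ins[[1]]), dim(ins[[2]]))
        af <- broadcast_to(ins[[1]], d); bf <- broadcast_to(ins[[2]], d)
        list(y = (af + bf) / 2, cache = list(da = dim(ins[[1]]), db = dim(ins[[2]])))
      },
      concat = {
        cc <- concat_fw(ins)
        list(y = cc$y, cache = cc$Cs)
      },
      maxpool = {
        mp <- cpp_maxpool_fw(ins[[1]], a$k, a$s, a$pad)
        list(y = mp$y, cache = list(idx = mp$idx, d = dim(ins[[1]])))
      },
      up2 = list(y = up2_fw(ins[[1]]), cache = NULL),
      gap = list(y = gap_fw(ins[[1]]), cache = dim(ins[[1]])),
      lap = list(y = local_avg_pool(ins[[1]], a$p), cache = dim(ins[[1]])),
      unpool = {
        dref <- dim(ins[[2]])
        list(y = local_unpool(ins[[1]], dref[2], dref[3]),
             cache = dim(ins[[1]])[2])
      },
      chanmix = {
        w <- if (is.na(node$share)) par$w else params[[node$share]]$w
        list(y = channel_mix_1d(ins[[1]], w), cache = ins[[1]])
      },
      blackbox = list(y = a$fwd(ins[[1]], par), cache = NULL),
      stop("unknown op: ", node$op)
    )
    outs[[i]] <- r$y
    if (keep) caches[[i]] <- r$cache
  }
  list(heads = outs[model$out_ids], outs = if (keep) outs else NULL,
       caches = caches, state = state)
}

## ---- backward -----------------------------------------------------------

backward_graph <- function(model, params, fw, dheads) {
  n <- length(model$nodes)
  gouts <- vector("list", n)
  for (j in seq_along(model$out_ids)) gouts[[model$out_ids[j]]] <- dheads[[j]]
  dparams <- vector("list", n)
  acc_par <- function(i, dp) {
    if (is.null(dparams[[i]])) dparams[[i]] <<- dp
    else dparams[[i]] <<- Map(`+`, dparams[[i]], dp)
  }
  outs <- fw$outs; caches <- fw$caches
  for (i in rev(seq_len(n))) {
    dy <- gouts[[i]]
    if (is.null(dy)) next
    node <- model$nodes[[i]]
    a <- node$attrs
    dins <- switch(node$op,
      conv = {
        g <- cpp_conv2d_bw(caches[[i]], params[[i]]$w, dy, a$s, a$pad, a$g,
                           isTRUE(a$bias))
        dp <- list(w = g$dw)
        if (isTRUE(a$bias)) dp$b <- g$db
        acc_par(i, dp)
        list(g$dx)
      },
      bn = {
        g <- bn_bw(caches[[i]], dy)
        acc_par(i, list(gamma = g$dgamma, beta = g$dbeta))
        list(g$dx)
      },
      silu = list(op_silu_bw(caches[[i]], dy)),
      relu = list(op_relu_bw(caches[[i]], dy)),
      sigmoid = list(op_sigmoid_bw(caches[[i]], dy)),
      add = list(dy, dy),
      mul = {
        ca <- caches[[i]]
        d <- dim(dy)
        list(reduce_like(dy * broadcast_to(ca$b, d), dim(ca$a)),
             reduce_like(dy * broadcast_to(ca$a, d), dim(ca$b)))
      },
      mean2 = {
        ca <- caches[[i]]
        list(reduce_like(dy / 2, ca$da), reduce_like(dy / 2, ca$db))
      },
      concat = {
        Cs <- caches[[i]]
        at <- 0L
        out <- vector("list", length(Cs))
        for (j in seq_along(Cs)) {
          out[[j]] <- dy[at + seq_len(Cs[j]), , , drop = FALSE]
          at <- at + Cs[j]
        }
        out
      },
      maxpool = {
        ca <- caches[[i]]
        list(cpp_maxpool_bw(dy, ca$idx, ca$d[1], ca$d[2], ca$d[3]))
      },
      up2 = list(up2_bw(dy)),
      gap = {
        d <- caches[[i]]
        list(array(as.vector(dy) / (d[2] * d[3]), d))
      },
      lap = {
        d <- caches[[i]]
        list(lap_bw(dy, d[1], d[2], d[3], a$p))
      },
      unpool = list(unpool_bw(dy, caches[[i]]), NULL),
      chanmix = {
        wi <- if (is.na(node$share)) i else node$share
        g <- chanmix_bw(caches[[i]], params[[wi]]$w, dy)
        acc_par(wi, list(w = g$dw))
        list(g$dx)
      },
      blackbox = stop("attention variant '", a$variant,
                      "' supports forward and profiling only", call. = FALSE),
      stop("unknown op: ", node$op)
    )
    for (j in seq_along(node$from)) {
      f <- node$from[j]
      if (f == 0L || is.null(dins[[j]])) next
      gouts[[f]] <- if (is.null(gouts[[f]])) dins[[j]] else gouts[[f]] + dins[[j]]
    }
    gouts[[i]] <- NULL  # free
  }
  dparams
}

## ---- shape inference ----------------------------------------------------

infer_shapes <- function(model, C0, H0, W0) {
  n <- length(model$nodes)
  sh <- vector("list", n)
  get <- function(f) if (f == 0L) c(C0, H0, W0) else sh[[f]]
  for (i in seq_len(n)) {
    node <- model$nodes[[i]]
    a <- node$attrs
    ins <- lapply(node$from, get)
    sh[[i]] <- switch(node$op,
      conv = c(a$cout, (ins[[1]][2] + 2 * a$pad - a$k) %/% a$s + 1,
               (ins[[1]][3] + 2 * a$pad - a$k) %/% a$s + 1),
      maxpool = c(ins[[1]][1], (ins[[1]][2] + 2 * a$pad - a$k) %/% a$s + 1,
                  (ins[[1]][3] + 2 * a$pad - a$k) %/% a$s + 1),
      concat = c(sum(vapply(ins, `[`, numeric(1), 1)), ins[[1]][2], ins[[1]][3]),
      up2 = c(ins[[1]][1], ins[[1]][2] * 2, ins[[1]][3] * 2),
      gap = c(ins[[1]][1], 1, 1),
      lap = c(ins[[1]][1], a$p, a$p),
      unpool = c(ins[[1]][1], ins[[2]][2], ins[[2]][3]),
      mul = ,
      mean2 = pmax(ins[[1]], ins[[2]]),
      ins[[1]])
  }
  sh
}
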