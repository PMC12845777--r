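# The attention plug-in zoo: shape contracts, gate ranges, hand-counted
# weight totals, the GEFA residual decomposition, and determinism.

specs_for <- function(C) list(
  se = attention_spec("se"),
  eca = attention_spec("eca"),
  ca = attention_spec("ca"),
  cbam = attention_spec("cbam"),
  mlca = attention_spec("mlca"),
  gefa = attention_spec("gefa", groups = if (C %% 32 == 0) 32L else 8L))

test_that("every attention variant preserves the feature-map shape", {
  x <- rand_fmap(128, 20, 20, 1)
  for (sp in specs_for(128)) {
    mod <- construct_attention(sp, 128, seed = 2)
    expect_identical(dim(attention_apply(mod, x)), dim(x))
  }
  # a second shape, non-square
  x2 <- rand_fmap(64, 10, 15, 2)
  for (sp in specs_for(64)) {
    mod <- construct_attention(sp, 64, seed = 2)
    expect_identical(dim(attention_apply(mod, x2)), dim(x2))
  }
})

test_that("gefa output decomposes as x + gate * enhanced with gate in (0,1)", {
  sp <- attention_spec("gefa", groups = 8L)
  for (seed in 1:4) {
    x <- rand_fmap(64, 12, 12, seed)
    mod <- construct_attention(sp, 64, seed = seed)
    r <- attention_apply(mod, x, detail = TRUE)
    expect_true(all(r$gate > 0) && all(r$gate < 1))
    expect_equal(r$y, x + r$gate * r$U, tolerance = 1e-12)
  }
})

test_that("gefa gate saturates when the mixer drives the logit to extremes", {
  # identity-preserving grouped weights: conv1 passes each group through its
  # centre tap, conv2 inverts it, normalisation starts at identity (running
  # statistics mean 0, variance 1), so U = x before gating.
  sp <- attention_spec("gefa", groups = 4L, group_width_factor = 1)
  C <- 16L
  mod <- construct_attention(sp, C, seed = 1)
  convs <- which(vapply(mod$model$nodes, function(n) n$op == "conv",
                        logical(1)))
  w1 <- mod$params[[convs[1]]]$w * 0   # (3,3,cg,Hh)
  for (o in seq_len(dim(w1)[4])) {
    g <- (o - 1) %/% (dim(w1)[4] / 4)  # group index
    w1[2, 2, (o - 1) %% (dim(w1)[3]) + 1, o] <- 1
  }
  mod$params[[convs[1]]]$w <- w1
  w2 <- mod$params[[convs[2]]]$w * 0   # (1,1,hg,C)
  for (o in seq_len(C)) w2[1, 1, (o - 1) %% dim(w2)[3] + 1, o] <- 1
  mod$params[[convs[2]]]$w <- w2
  mixes <- which(vapply(mod$model$nodes, function(n)
    n$op == "chanmix" && is.na(n$share), logical(1)))
  x <- abs(rand_fmap(C, 10, 10, 5)) + 0.5  # positive descriptors
  silu_x <- x / (1 + exp(-x))              # U under identity weights
  mod$params[[mixes[1]]]$w <- c(0, 50, 0)  # gate logit >> 0 -> A -> 1
  r <- attention_apply(mod, x, detail = TRUE)
  expect_true(all(r$gate > 0.999))
  expect_equal(r$U, silu_x, tolerance = 1e-4)
  expect_equal(r$y, x + silu_x, tolerance = 1e-3)
  mod$params[[mixes[1]]]$w <- c(0, -50, 0) # gate logit << 0 -> A -> 0
  y_lo <- attention_apply(mod, x)
  expect_equal(y_lo, x, tolerance = 1e-3)
})

test_that("learned-weight totals match closed-form hand counts", {
  # SE at C = 64, r = 4: two bias-free projections, 2 * 64 * 16
  se <- construct_attention(attention_spec("se"), 64)
  expect_equal(se$n_params, 2048)
  expect_equal(attention_param_count(attention_spec("se"), 64), 2048)
  # ECA at C = 256: a 5-tap mixer
  expect_equal(construct_attention(attention_spec("eca"), 256)$n_params, 5)
  # GEFA closed form vs enumerated weights across (C, spec) combinations
  combos <- list(
    list(C = 64, sp = attention_spec("gefa", groups = 8L)),
    list(C = 128, sp = attention_spec("gefa", groups = 16L,
                                      group_width_factor = 1.5)),
    list(C = 256, sp = attention_spec("gefa", groups = 32L,
                                      group_kernel = 1L)),
    list(C = 96, sp = attention_spec("gefa", groups = 4L, share_mixer = FALSE)))
  for (cb in combos) {
    mod <- construct_attention(cb$sp, cb$C)
    expect_equal(mod$n_params, attention_param_count(cb$sp, cb$C))
  }
  # hand count of one combination in full: C=64, G=8, k=3, f=2.875
  sp <- attention_spec("gefa", groups = 8L, group_kernel = 3L,
                       group_width_factor = 2.875)
  hg <- max(1, floor(2.875 * 64 / 8 + 0.5))      # hidden width per group
  hand <- 9 * (64 / 8) * hg * 8 + 2 * 8 * hg +   # grouped 3x3 conv + norm
    hg * (64 / 8) * 8 + 2 * 64 +                 # grouped 1x1 conv + norm
    eca_kernel_size(64)                          # shared mixer
  expect_equal(attention_param_count(sp, 64), hand)
})

test_that("all gates stay strictly inside (0,1) for random inputs", {
  # the gate is the sigmoid immediately preceding the final product
  for (v in c("se", "eca", "mlca")) {
    sp <- attention_spec(v)
    mod <- construct_attention(sp, 32, seed = 3)
    sig <- max(which(vapply(mod$model$nodes, function(n) n$op == "sigmoid",
                            logical(1))))
    x <- rand_fmap(32, 8, 8, 7)
    fw <- forward_graph(mod$model, mod$params, x, keep = TRUE)
    g <- fw$outs[[sig]]
    expect_true(all(g > 0) && all(g < 1))
  }
})

test_that("identical specs and seeds give identical modules", {
  sp <- attention_spec("gefa", groups = 8L)
  a <- construct_attention(sp, 64, seed = 11)
  b <- construct_attention(sp, 64, seed = 11)
  expect_identical(a$params, b$params)
  x <- rand_fmap(64, 10, 10, 1)
  expect_identical(attention_apply(a, x), attention_apply(b, x))
})

test_that("gefa rejects invalid channel/grid combinations", {
  expect_error(construct_attention(attention_spec("gefa", groups = 32L), 48),
               "divisible")
  mod <- construct_attention(attention_spec("gefa", groups = 8L), 64)
  expect_error(attention_apply(mod, rand_fmap(64, 3, 3)), "smaller")
  expect_error(attention_spec("nope"), "unknown")
})
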