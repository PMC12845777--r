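# Detector blocks and graph assembly: parameter bookkeeping, depth scaling,
# the attention slot contract and the forward-pass stride layout.

test_that("conv block parameter counts match hand counts", {
  expect_equal(build_conv_block(3, 32, k = 6, s = 2)$n_params,
               3 * 32 * 36 + 64)          # 3520
  expect_equal(build_conv_block(64, 64, k = 1, s = 1)$n_params,
               64 * 64 + 128)             # 4224
  # stride-1 1x1 preserves the spatial extent
  b <- build_conv_block(4, 8, k = 1, s = 1)
  expect_identical(dim(b$apply(rand_fmap(4, 9, 11))), c(8L, 9L, 11L))
})

test_that("depth multiplier rounds repeats with a floor of one", {
  expect_equal(gefay:::scale_depth(3, 0.33), 1)   # round(0.99)
  expect_equal(gefay:::scale_depth(9, 0.33), 3)   # round(2.97)
  expect_equal(gefay:::scale_depth(6, 0.33), 2)
  expect_equal(gefay:::scale_depth(3, 0.1), 1)    # floor at one
})

test_that("C3 parameter count matches the closed-form sum", {
  conv_p <- function(c1, c2, k) k * k * c1 * c2 + 2 * c2
  hand <- conv_p(64, 32, 1) * 2 +                 # two entry branches
    conv_p(64, 64, 1) +                           # exit fusion
    conv_p(32, 32, 1) + conv_p(32, 32, 3)         # one bottleneck
  expect_equal(build_c3(64, 64, n = 1)$n_params, hand)
  expect_error(build_c3(64, 63), "even")
})

test_that("the attention slot of AttentionC3 honours its contract", {
  plain <- build_c3(64, 64, n = 1)
  none <- build_attention_c3(64, 64, n = 1, spec = attention_spec("none"))
  expect_equal(none$n_params, plain$n_params)
  se <- build_attention_c3(64, 64, n = 1, spec = attention_spec("se"))
  expect_equal(se$n_params, plain$n_params + 2048)
  x <- rand_fmap(64, 16, 16, 3)
  d0 <- dim(plain$apply(x))
  for (v in c("se", "eca", "ca", "cbam", "mlca", "gefa")) {
    sp <- attention_spec(v, groups = 8L)
    blk <- build_attention_c3(64, 64, n = 1, spec = sp)
    expect_identical(dim(blk$apply(x)), d0)
  }
})

test_that("head parameters depend on the class count exactly as expected", {
  m80 <- build_model(model_spec(nc = 80L))
  m20 <- build_model(model_spec(nc = 20L))
  head_params <- function(m) {
    bd <- count_parameters(m)$breakdown
    sum(bd$params[bd$kind == "head"])
  }
  expect_equal(head_params(m80), 229245)
  expect_equal(head_params(m20), 67425)
  # the class count touches only the head: 2697 weights per class at width 0.5
  t80 <- count_parameters(m80)$total_params
  t20 <- count_parameters(m20)$total_params
  expect_equal(t80 - t20, 2697 * (80 - 20))
})

test_that("attention placement never touches the head", {
  sp <- attention_spec("gefa", groups = 32L)
  for (nc in c(12L, 20L)) {
    bb <- count_parameters(build_model(model_spec(nc = nc)))$breakdown
    bg <- count_parameters(build_model(model_spec(nc = nc,
                                                  attention = sp)))$breakdown
    expect_equal(bg$params[bg$kind == "head"], bb$params[bb$kind == "head"])
  }
})

test_that("identical specs build identical layer records and weights", {
  s <- model_spec(nc = 12L, attention = attention_spec("gefa", groups = 32L))
  a <- build_model(s, seed = 5)
  b <- build_model(s, seed = 5)
  expect_identical(a$records, b$records)
  expect_identical(a$params, b$params)
})

test_that("forward pass emits three scales at strides 8/16/32", {
  m <- build_model(model_spec(nc = 2L, width_multiple = 0.125,
                              input_size = 64L))
  x <- rand_fmap(3, 64, 64, 1)
  h <- model_forward(m, x)
  expect_length(h, 3)
  expect_identical(vapply(h, function(z) dim(z)[2], integer(1)),
                   c(8L, 4L, 2L))
  expect_identical(vapply(h, function(z) dim(z)[1], integer(1)),
                   rep(3L * (2L + 5L), 3))
  # a different input size scales the grids
  h2 <- model_forward(m, rand_fmap(3, 96, 96, 1))
  expect_identical(vapply(h2, function(z) dim(z)[2], integer(1)),
                   c(12L, 6L, 3L))
  # the batch axis (a list of images) is preserved
  hb <- model_forward(m, list(x, x))
  expect_length(hb, 2)
  expect_identical(hb[[1]], hb[[2]])
  expect_error(model_forward(m, rand_fmap(3, 60, 60)), "divisible")
})

test_that("channel bookkeeping is consistent along the graph", {
  m <- build_model(model_spec(nc = 12L,
                              attention = attention_spec("gefa", groups = 32L)))
  sh <- gefay:::infer_shapes(m, 3L, 640L, 640L)
  chan <- function(f) if (f == 0L) 3 else sh[[f]][1]
  for (node in m$nodes) {
    if (node$op == "concat") {
      ins <- vapply(node$from, chan, numeric(1))
      expect_equal(sh[[node$i]][1], sum(ins))
    }
    if (node$op == "conv")
      expect_equal(chan(node$from[1]), node$attrs$cin)
  }
})
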