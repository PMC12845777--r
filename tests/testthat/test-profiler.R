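# Complexity accounting: enumeration vs analytic oracles, truncation
# convention, FLOP conventions, monotonicity and the calibration search.

test_that("parameter totals agree with an independent weight enumeration", {
  m <- build_model(model_spec(nc = 20L,
                              attention = attention_spec("gefa", groups = 32L)))
  cr <- count_parameters(m)
  enum <- 0
  for (p in m$params)
    if (!is.null(p)) for (a in p) enum <- enum + length(a)
  expect_equal(cr$total_params, enum)
  expect_equal(sum(cr$breakdown$params), cr$total_params)
})

test_that("megaparameter figures use truncation, not rounding", {
  expect_equal(floor(7235389 / 1e4) / 100, 7.23)
  m <- build_model(model_spec(nc = 80L))
  cr <- count_parameters(m)
  expect_equal(cr$params_mega, floor(cr$total_params / 1e4) / 100)
})

test_that("bare-MAC FLOPs match an independent per-layer hand count", {
  # independent oracle: walk the known v6 layout arithmetic directly
  macs <- 0
  conv <- function(c1, c2, k, s, hw) { h <- hw / s
    macs <<- macs + k * k * c1 * c2 * h * h; h }
  c3 <- function(c1, c2, n, hw) { ch <- c2 / 2
    conv(c1, ch, 1, 1, hw); conv(c1, ch, 1, 1, hw)
    for (i in seq_len(n)) { conv(ch, ch, 1, 1, hw); conv(ch, ch, 3, 1, hw) }
    conv(2 * ch, c2, 1, 1, hw); hw }
  h <- conv(3, 32, 6, 2, 640); h <- conv(32, 64, 3, 2, h); c3(64, 64, 1, h)
  h <- conv(64, 128, 3, 2, h); c3(128, 128, 2, h); h3 <- h
  h <- conv(128, 256, 3, 2, h); c3(256, 256, 3, h); h4 <- h
  h <- conv(256, 512, 3, 2, h); c3(512, 512, 1, h)
  conv(512, 256, 1, 1, h); conv(1024, 512, 1, 1, h)      # SPPF
  conv(512, 256, 1, 1, h); c3(512, 256, 1, h4)
  conv(256, 128, 1, 1, h4); c3(256, 128, 1, h3)
  conv(128, 128, 3, 2, h3); c3(256, 256, 1, h4)
  conv(256, 256, 3, 2, h4); c3(512, 512, 1, h)
  macs <- macs + (128 * h3^2 + 256 * h4^2 + 512 * h^2) * 3 * 85
  m <- build_model(model_spec(nc = 80L))
  expect_equal(count_flops(m, convention = "mac")$flops, 2 * macs)
})

test_that("the calibrated convention reproduces both baseline GFLOPS cells", {
  expect_equal(calibrate_flop_convention(), "full")
  g80 <- count_flops(build_model(model_spec(nc = 80L)))$flops_giga
  g20 <- count_flops(build_model(model_spec(nc = 20L)))$flops_giga
  expect_equal(round(g80, 1), 16.6)
  expect_equal(round(g20, 1), 16.1)
})

test_that("adding attention never decreases parameters or FLOPs", {
  base <- complexity_report(build_model(model_spec(nc = 20L)))
  for (v in c("se", "eca", "ca", "cbam", "mlca", "gefa")) {
    sp <- attention_spec(v, groups = 32L)
    cr <- complexity_report(build_model(model_spec(nc = 20L, attention = sp)))
    expect_gte(cr$total_params, base$total_params)
    expect_gte(cr$flops, base$flops)
  }
})

test_that("the attention parameter delta is independent of the class count", {
  sp <- attention_spec("gefa", groups = 32L)
  deltas <- vapply(c(12L, 20L, 80L), function(nc) {
    count_parameters(build_model(model_spec(nc = nc, attention = sp)))$total_params -
      count_parameters(build_model(model_spec(nc = nc)))$total_params
  }, numeric(1))
  expect_equal(deltas[1], deltas[2])
  expect_equal(deltas[2], deltas[3])
})

test_that("calibration lands inside the feasibility window for both nc", {
  b20 <- count_parameters(build_model(model_spec(nc = 20L)))$total_params
  b80 <- count_parameters(build_model(model_spec(nc = 80L)))$total_params
  lo <- max(7390000 - b20, 7550000 - b80)   # interval arithmetic on exact counts
  hi <- min(7400000 - b20, 7560000 - b80)
  expect_lt(lo, hi)                         # the window is non-empty
  cal <- calibrate_gefa()
  expect_s3_class(cal, "gefa_calibration")
  expect_true(cal$delta >= lo && cal$delta < hi)
  expect_equal(unname(cal$cells), c(7.39, 7.55))
  # no attention means delta 0, which must lie outside the window
  expect_lt(0, lo)
})

test_that("an empty feasible set yields a near-miss diagnostic, not a pick", {
  bad <- calibrate_gefa(targets = c(nc20 = 7.10, nc80 = 7.55))
  expect_s3_class(bad, "gefa_calibration_failure")
  expect_false(bad$success)
  expect_true(nrow(bad$near_misses) > 0)
  expect_true(all(bad$near_misses$miss > 0))
  expect_output(print(bad), "near")
})

test_that("the SE delta from the closed form matches the built model", {
  sp <- attention_spec("se", reduction = 4L)
  slots <- c("P2", "P3", "P4", "P5", "N1", "N2", "N3", "N4")
  mg <- build_model(model_spec(nc = 20L, attention = sp,
                               attention_placement = slots))
  mb <- build_model(model_spec(nc = 20L))
  chans <- c(64, 128, 256, 512, 256, 128, 256, 512)
  hand <- sum(vapply(chans, function(C) 2 * C * ceiling(C / 4), numeric(1)))
  expect_equal(count_parameters(mg)$total_params -
                 count_parameters(mb)$total_params, hand)
})

test_that("the variant table reports and round-trips consistently", {
  specs <- list(none = attention_spec("none"), se = attention_spec("se"),
                eca = attention_spec("eca"),
                gefa = attention_spec("gefa", groups = 32L))
  df <- table_report(specs, nc = 20L)
  expect_equal(df$params_m[1], 7.07)
  expect_equal(df$gflops[1], 16.1)
  expect_true(all(df$params_m >= df$params_m[1]))
  back <- parse_table_report(format_table_report(df))
  expect_equal(back$params_m, df$params_m)
  expect_equal(back$gflops, df$gflops)
  expect_equal(back$attention, df$attention)
})
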