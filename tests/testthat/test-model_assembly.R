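# Variant assembly, parameter/FLOP ledgers and the configuration solver.

test_that("MCRT subtotal and stem+head closure are exact", {
  proposed <- build_variant(variant_spec("Proposed"))
  cnn1 <- build_variant(variant_spec("CNN-1"))
  p_prop <- count_params(proposed)$total
  p_cnn1 <- count_params(cnn1)$total
  # three MCRT blocks at mixed ratios
  mcrt_total <- sum(sapply(c(16L, 32L, 64L), function(C) {
    renalnet:::module_param_count(mcrt_block(C))
  }))
  expect_equal(mcrt_total, 156674)
  # stem + transitions + classifier head closure
  expect_equal(p_cnn1 - mcrt_total, 26212)
  # GCDL head total by difference
  expect_equal(p_prop - p_cnn1, 30288)
})

test_that("SE-ratio policy swaps change totals by the closed-form deltas", {
  p <- sapply(c("GCNN-5", "GCNN-6", "GCNN-7", "Proposed"), function(v) {
    count_params(build_variant(variant_spec(v)))$total
  })
  expect_equal(p[["GCNN-5"]] - p[["GCNN-6"]], 8148)
  expect_equal(p[["GCNN-6"]] - p[["GCNN-7"]], 4074)
  expect_equal(p[["GCNN-5"]] - p[["Proposed"]], 6790)
})

test_that("single SE unit at C=64, r=2 counts 4192 parameters", {
  expect_equal(renalnet:::module_param_count(se_unit(64, 2)), 4192)
})

test_that("FLOP accounting follows the closed form and is additive", {
  # one 3x3 convolution 16->16 at 224^2 under 'same' padding
  l <- renalnet:::layer_conv(16, 16, k = 3)
  expect_equal(2 * l$macs(c(224L, 224L, 16L)), 2 * 224 * 224 * 9 * 16 * 16)
  expect_equal(2 * l$macs(c(224L, 224L, 16L)), 231211008)
  m <- build_variant(variant_spec("Proposed"), input_size = 32)
  fl32 <- count_flops(m, 32)
  expect_equal(fl32$total_flops, 2 * sum(fl32$table$macs))
  # doubling input size quadruples conv MACs; the FC layer is unchanged
  fl64 <- count_flops(m, 64)
  conv32 <- fl32$table[fl32$table$kind == "conv", ]
  conv64 <- fl64$table[fl64$table$kind == "conv", ]
  expect_equal(conv64$macs, 4 * conv32$macs)
  expect_equal(fl32$table$macs[fl32$table$layer == "head_fc"],
               fl64$table$macs[fl64$table$layer == "head_fc"])
})

test_that("forward pass yields a probability vector summing to one", {
  set.seed(3)
  m <- build_variant(variant_spec("Proposed"), input_size = 8)
  x <- array(rnorm(8 * 8 * 3 * 3), c(8, 8, 3, 3))
  out <- m$forward(x, train = TRUE)
  expect_equal(colSums(out$probs), rep(1, 3), tolerance = 1e-6)
  expect_true(all(out$probs >= 0))
})

test_that("illegal flag combinations name the nearest legal variant", {
  spec <- variant_spec("Proposed")
  spec$use_mcrt <- FALSE
  spec$use_am <- FALSE     # (F, T, F) matches no row
  expect_error(build_variant(spec), "nearest legal row")
  expect_error(variant_spec("GCNN-9"), "unknown variant")
})

test_that("ledger reports round-trip through CSV with consistent totals", {
  m <- build_variant(variant_spec("GCNN-2"), input_size = 32)
  pl <- count_params(m)
  f <- tempfile(fileext = ".csv")
  ledger_report(pl, f)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$params[back$layer == "TOTAL"], pl$total)
  expect_equal(sum(back$params[back$layer != "TOTAL"]), pl$total)
  fl <- count_flops(m, 32)
  ledger_report(fl, f)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$macs[back$layer == "TOTAL"], fl$total_macs)
  unlink(f)
})

test_that("the configuration solver reproduces the frozen reference widths", {
  cfg <- solve_reference_config()
  expect_equal(cfg$gcdl, renalnet_config()$gcdl)
  cand <- attr(cfg, "candidates")
  expect_true(nrow(cand) >= 1)
  # infeasible targets fail loudly
  bad <- renalnet_reference_totals()
  bad$params[["Proposed"]] <- bad$params[["Proposed"]] + 1
  expect_error(solve_reference_config(bad), "sub-budgets|residuals|FLOP")
})

test_that("disabled MCRT stages are exact identity passthroughs", {
  set.seed(4)
  m2 <- build_variant(variant_spec("GCNN-2"), input_size = 8)
  expect_null(m2$mcrt1)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3, 1))
  out <- m2$forward(x)
  expect_equal(dim(out$probs), c(4L, 1L))
})
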