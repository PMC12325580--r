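# MCRT blocks and squeeze-and-excitation units.

test_that("se_squeeze reduces a map to per-channel spatial means", {
  v <- 3.7
  const_map <- array(v, c(5, 4, 6))
  expect_equal(se_squeeze(const_map), rep(v, 6))
  m <- array(c(1, 3, 2, 5), c(2, 2, 1))   # column-major: [[1,2],[3,5]]
  expect_equal(se_squeeze(m), 2.75)
  big <- array(rnorm(7 * 7 * 64), c(7, 7, 64))
  expect_length(se_squeeze(big), 64)
})

test_that("se_excite gates channels through the two-layer bottleneck", {
  # zero weights: sigmoid(0) = 0.5 for every channel
  u <- se_unit(6, 2)
  u$fc1$set_params(list(w = matrix(0, 3, 6), b = numeric(3)))
  u$fc2$set_params(list(w = matrix(0, 6, 3), b = numeric(6)))
  y <- array(rnorm(4 * 4 * 6), c(4, 4, 6))
  expect_equal(se_excite(se_squeeze(y), u, y), 0.5 * y)
  # weight shapes at C = 64, r = 2
  u64 <- se_unit(64, 2)
  expect_equal(dim(u64$fc1$w), c(32L, 64L))
  expect_equal(dim(u64$fc2$w), c(64L, 32L))
  # random unit against a straight-line evaluation
  set.seed(42)
  u4 <- se_unit(4, 2)
  y4 <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  s <- se_squeeze(y4)
  gate <- naive_se_gate(s, u4$fc1$w, u4$fc1$b, u4$fc2$w, u4$fc2$b)
  expected <- y4
  for (c in 1:4) expected[, , c] <- y4[, , c] * gate[c]
  expect_equal(se_excite(s, u4, y4), expected, tolerance = 1e-12)
  # gate boundedness
  expect_true(all(gate > 0 & gate < 1))
})

test_that("se_excite with fixed descriptor is exactly linear in the map", {
  set.seed(1)
  u <- se_unit(4, 4)
  y <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  s <- se_squeeze(y)
  base <- se_excite(s, u, y)
  y2 <- y
  y2[, , 2] <- 3 * y[, , 2]
  scaled <- se_excite(s, u, y2)
  expect_equal(scaled[, , 2], 3 * base[, , 2], tolerance = 1e-12)
  expect_equal(scaled[, , -2], base[, , -2], tolerance = 1e-12)
})

test_that("se_unit rejects non-integral reduced widths", {
  expect_error(se_unit(6, 4), "positive integer")
})

test_that("conv_path preserves shape, zeroes out with zero weights, and checks channels", {
  p <- conv_path(16, 2)
  x <- array(rnorm(8 * 8 * 16), c(8, 8, 16))
  expect_equal(dim(conv_path_forward(x, p)), c(8L, 8L, 16L))
  renalnet:::module_zero_params(p)
  expect_true(all(conv_path_forward(x, p, train = TRUE) == 0))
  bad <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  expect_error(conv_path_forward(bad, p), "C=16.*C=4")
})

test_that("mcrt block with zero parameters is an exact identity", {
  for (C in c(8L, 16L)) {
    blk <- mcrt_block(C)
    renalnet:::module_zero_params(blk)
    x <- array(rnorm(4 * 4 * C), c(4, 4, C))
    expect_identical(mcrt_forward(x, blk, train = TRUE), x)
    # input gradient of the identity path alone is 1 per element
    blk$forward(renalnet:::as_batch(x), train = TRUE)
    g1 <- blk$backward(array(1, c(4, 4, C, 1)))
    expect_equal(g1, array(1, c(4, 4, C, 1)))
  }
})

test_that("mcrt analytic gradient matches finite differences", {
  set.seed(13)
  blk <- mcrt_block(4, c(2, 2, 4))
  x <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  expect_lt(mcrt_gradient_check(blk, x, eps = 1e-4, seed = 3), 1e-3)
  # deviation is insensitive to path order: same paths, permuted
  blk2 <- mcrt_block(4, c(4, 2, 2))
  blk2$paths[[1]] <- blk$paths[[3]]
  blk2$paths[[2]] <- blk$paths[[1]]
  blk2$paths[[3]] <- blk$paths[[2]]
  blk2$children <- blk2$paths
  expect_equal(mcrt_forward(x, blk2, train = TRUE),
               mcrt_forward(x, blk, train = TRUE), tolerance = 1e-12)
  expect_lt(mcrt_gradient_check(blk2, x, eps = 1e-4, seed = 3), 1e-3)
})

test_that("parameter algebra holds for SE units and MCRT blocks", {
  for (C in c(16L, 32L, 64L)) {
    for (r in c(2L, 4L, 8L)) {
      expect_equal(renalnet:::module_param_count(se_unit(C, r)),
                   2 * C^2 / r + C / r + C)
    }
    expect_equal(renalnet:::module_param_count(mcrt_block(C, c(2, 4, 8))),
                 27 * C^2 + 15 * C +
                   sum(sapply(c(2, 4, 8), function(r) 2 * C^2 / r + C / r + C)))
  }
  # the three reference blocks at mixed ratios and the C = 16 worked example
  expect_equal(renalnet:::module_param_count(mcrt_block(16)), 7662)
  expect_equal(sum(sapply(c(16L, 32L, 64L), function(C) {
    renalnet:::module_param_count(mcrt_block(C))
  })), 156674)
})
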