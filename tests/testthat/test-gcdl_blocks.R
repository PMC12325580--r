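# GCDL head: strided fusion, global pooling, attention gate, dilated block.

test_that("strided fusion aligns all stages to the coarsest spatial size", {
  for (S in c(8L, 16L, 56L, 224L)) {
    fb <- fusion_block()
    x1 <- array(rnorm(S * S * 16), c(S, S, 16))
    x2 <- array(rnorm((S / 2)^2 * 32), c(S / 2, S / 2, 32))
    x3 <- array(rnorm((S / 4)^2 * 64), c(S / 4, S / 4, 64))
    y <- strided_fusion(x1, x2, x3, fb)
    expect_equal(dim(y)[1:2], c(S / 4, S / 4))
    expect_equal(dim(y)[3], 28L)
  }
})

test_that("strided fusion rejects misaligned spatial sizes and zeroes out", {
  fb <- fusion_block()
  x1 <- array(0, c(8, 8, 16)); x2 <- array(0, c(8, 8, 32))
  x3 <- array(0, c(2, 2, 64))
  expect_error(strided_fusion(x1, x2, x1, fb), "4:2:1")
  renalnet:::module_zero_params(fb)
  xr1 <- array(rnorm(8 * 8 * 16), c(8, 8, 16))
  xr2 <- array(rnorm(4 * 4 * 32), c(4, 4, 32))
  xr3 <- array(rnorm(2 * 2 * 64), c(2, 2, 64))
  out <- strided_fusion(xr1, xr2, xr3, fb, train = TRUE)
  expect_true(all(out == 0))
  expect_equal(dim(out)[1:2], c(2L, 2L))
})

test_that("global_pool computes per-channel means and is idempotent at 1x1", {
  expect_equal(global_pool(array(2.5, c(3, 3, 4))), rep(2.5, 4))
  m <- array(c(1, 1, 1, 1, 0, 4, 2, 6), c(2, 2, 2))
  expect_equal(global_pool(m), c(1, 3))
  one <- array(c(7, -2), c(1, 1, 2))
  expect_equal(global_pool(one), c(7, -2))
})

test_that("attention scaling is channel-selective and loop-exact", {
  x3 <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  expect_equal(attention_scale(rep(1, 4), x3), x3)
  g <- c(0, 0, 2, 0)
  y <- attention_scale(g, x3)
  expect_true(all(y[, , -3] == 0))
  expect_equal(y[, , 3], 2 * x3[, , 3])
  set.seed(9)
  gr <- runif(4)
  yo <- x3
  for (a in 1:3) for (b in 1:3) for (c in 1:4) {
    yo[a, b, c] <- gr[c] * x3[a, b, c]
  }
  expect_equal(attention_scale(gr, x3), yo, tolerance = 1e-12)
  expect_error(attention_scale(rep(1, 3), x3), "does not match")
})

test_that("attention gate projects the pooled descriptor to the stage-3 width", {
  set.seed(2)
  am <- attention_gate(cf = 28, hidden = 48, out_width = 64)
  x_out <- array(rnorm(4 * 4 * 28), c(4, 4, 28, 1))
  x3 <- array(rnorm(4 * 4 * 64), c(4, 4, 64, 1))
  y <- am$forward(x_out, x3, train = TRUE)
  expect_equal(dim(y), dim(x3))
  g <- as.numeric(am$g)
  expect_length(g, 64)
  expect_true(all(g > 0 & g < 1))
  expect_error(am$forward(x3, x3), "expects 28")
})

test_that("dilated depthwise branches have the dilated 3x3 stencil support", {
  for (d in c(1L, 2L, 4L, 6L)) {
    S <- 4L * d + 1L
    l <- renalnet:::layer_conv(1, 1, k = 3, dilation = d, groups = 1, bias = FALSE)
    l$set_params(list(w = array(1, c(3, 3, 1, 1))))
    x <- array(0, c(S, S, 1, 1))
    mid <- (S + 1L) %/% 2L
    x[mid, mid, 1, 1] <- 1
    y <- l$forward(x)[, , 1, 1]
    on_idx <- which(y != 0, arr.ind = TRUE)
    offs <- unique(as.vector(on_idx - mid))
    expect_setequal(offs, c(-d, 0L, d))
    expect_equal(sum(y != 0), 9)
  }
  blk <- adsc_block()
  expect_equal(blk$dilations, c(1L, 2L, 4L, 6L))
})

test_that("adsc block preserves spatial size and zeroes out with zero weights", {
  blk <- adsc_block(cf = 28, branch_width = 27)
  x <- array(rnorm(6 * 6 * 28), c(6, 6, 28))
  y <- adsc_forward(x, blk, train = TRUE)
  expect_equal(dim(y), c(6L, 6L, 64L))
  renalnet:::module_zero_params(blk)
  expect_true(all(adsc_forward(x, blk, train = TRUE) == 0))
})

test_that("gcdl head yields a fixed-length feature vector and supports ablation", {
  S <- 16L
  x1 <- array(rnorm(S * S * 16), c(S, S, 16))
  x2 <- array(rnorm((S / 2)^2 * 32), c(S / 2, S / 2, 32))
  x3 <- array(rnorm((S / 4)^2 * 64), c(S / 4, S / 4, 64))
  full <- gcdl_head()
  v <- gcdl_forward(x1, x2, x3, full, train = TRUE)
  expect_length(v, 64)
  # batched input gives one column per sample
  xb1 <- array(rnorm(S * S * 16 * 3), c(S, S, 16, 3))
  xb2 <- array(rnorm((S / 2)^2 * 32 * 3), c(S / 2, S / 2, 32, 3))
  xb3 <- array(rnorm((S / 4)^2 * 64 * 3), c(S / 4, S / 4, 64, 3))
  vb <- gcdl_forward(xb1, xb2, xb3, full, train = TRUE)
  expect_equal(dim(vb), c(64L, 3L))
  # reduced variants drop the corresponding sub-block
  only_adsc <- gcdl_head(use_adsc = TRUE, use_am = FALSE)
  only_am <- gcdl_head(use_adsc = FALSE, use_am = TRUE)
  expect_null(only_adsc$am)
  expect_null(only_am$adsc)
  expect_error(gcdl_head(use_adsc = FALSE, use_am = FALSE), "at least one")
  # zero-weight head maps anything to zero
  zh <- gcdl_head()
  renalnet:::module_zero_params(zh)
  expect_true(all(gcdl_forward(x1, x2, x3, zh, train = TRUE) == 0))
})

test_that("gcdl backward routes exact gradients to all three stage inputs", {
  set.seed(21)
  S <- 8L
  head <- gcdl_head()
  x1 <- array(rnorm(S * S * 16), c(S, S, 16, 1))
  x2 <- array(rnorm((S / 2)^2 * 32), c(S / 2, S / 2, 32, 1))
  x3 <- array(rnorm((S / 4)^2 * 64), c(S / 4, S / 4, 64, 1))
  probe <- array(rnorm((S / 4)^2 * 64), c(S / 4, S / 4, 64, 1))
  renalnet:::module_zero_grads(head)
  head$forward(x1, x2, x3, train = TRUE)
  g <- head$backward(probe)
  h <- function(a, b, cc) sum(probe * head$forward(a, b, cc, train = TRUE))
  eps <- 1e-5
  for (i in sample(length(x3), 5)) {
    xp <- x3; xp[i] <- xp[i] + eps
    xm <- x3; xm[i] <- xm[i] - eps
    expect_equal(g$gx3[i], (h(x1, x2, xp) - h(x1, x2, xm)) / (2 * eps),
                 tolerance = 1e-3)
  }
  for (i in sample(length(x1), 5)) {
    xp <- x1; xp[i] <- xp[i] + eps
    xm <- x1; xm[i] <- xm[i] - eps
    expect_equal(g$gx1[i], (h(xp, x2, x3) - h(xm, x2, x3)) / (2 * eps),
                 tolerance = 1e-3)
  }
})
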