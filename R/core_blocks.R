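# Multiple Channel Residual Transformation (MCRT) building blocks.
#
# An MCRT stage maps an (H, W, C) feature map to the same shape through three
# parallel paths plus an identity connection:
#
#   path i:  Conv3x3(C -> C, bias) -> BN -> ReLU -> SE(r_i) -> BN
#   output:  X + path1(X) + path2(X) + path3(X)
#
# The SE (squeeze-and-excitation) gate pools each channel to its spatial mean
# ("squeeze"), passes the C-vector through a two-layer bottleneck of width C/r
# with ReLU then sigmoid ("excitation"), and rescales each channel by its gate
# value. The three paths use excitation ratios (2, 4, 8) in the reference
# model, giving three effective receptive depths per stage.

#' Squeeze-and-excitation unit
#'
#' Channel-attention gate: global average pooling followed by a two-layer
#' bottleneck (`C -> C/r -> C`, ReLU then sigmoid) whose output rescales each
#' channel of the input map. Both dense layers carry biases; the unit holds
#' `2*C^2/r + C/r + C` trainable parameters.
#'
#' @param C Number of channels.
#' @param r Excitation ratio; `C/r` must be a positive integer.
#' @return A module environment with `$forward()`/`$backward()` methods.
#' @export
se_unit <- function(C, r) {
  C <- as.integer(C); r <- as.integer(r)
  if (C %% r != 0L || C %/% r < 1L) {
    stop(sprintf("SE unit: reduced width C/r must be a positive integer (C=%d, r=%d)",
                 C, r))
  }
  self <- new_module("se", sprintf("se_r%d", r))
  self$C <- C; self$r <- r
  hid <- C %/% r
  self$fc1 <- layer_dense(C, hid, bias = TRUE, name = "se_fc1")
  self$fc2 <- layer_dense(hid, C, bias = TRUE, name = "se_fc2")
  self$children <- list(self$fc1, self$fc2)

  self$gate <- function(s, train = FALSE) {
    a <- self$fc1$forward(s, train)
    self$relu_mask <- a > 0
    z <- self$fc2$forward(a * self$relu_mask, train)
    g <- 1 / (1 + exp(-z))
    self$g <- g
    g
  }
  self$gate_backward <- function(gg) {
    gz <- gg * self$g * (1 - self$g)
    ga <- self$fc2$backward(gz)
    self$fc1$backward(ga * self$relu_mask)
  }
  self$forward <- function(y, train = FALSE) {
    y <- as_batch(y)
    d <- dim(y)
    self$y <- y; self$ydim <- d
    dim(y) <- c(d[1] * d[2], d[3] * d[4])
    s <- matrix(colMeans(y), d[3], d[4])
    dim(y) <- d
    g <- self$gate(s, train)
    y * array(rep(as.numeric(g), each = d[1] * d[2]), dim = d)
  }
  self$backward <- function(gy) {
    d <- self$ydim
    gexp <- array(rep(as.numeric(self$g), each = d[1] * d[2]), dim = d)
    # gradient into the gate vector
    tmp <- gy * self$y
    dim(tmp) <- c(d[1] * d[2], d[3] * d[4])
    gg <- matrix(colSums(tmp), d[3], d[4])
    gs <- self$gate_backward(gg)
    gy_direct <- gy * gexp
    gy_pool <- array(rep(as.numeric(gs), each = d[1] * d[2]) / (d[1] * d[2]),
                     dim = d)
    gy_direct + gy_pool
  }
  self$out_shape <- function(s) s
  self$macs <- function(s) self$fc1$macs(NULL) + self$fc2$macs(NULL)
  self
}

#' One MCRT convolution path
#'
#' `Conv3x3 (bias) -> BN -> ReLU -> SE(r) -> BN`, shape preserving
#' ('same' padding, stride 1, equal input and output width).
#'
#' @param C Path width (input = output channels).
#' @param r Excitation ratio of the path's SE unit.
#' @return A module environment.
#' @export
conv_path <- function(C, r) {
  self <- new_module("conv_path", sprintf("path_r%d", r))
  self$C <- as.integer(C); self$r <- as.integer(r)
  self$conv <- layer_conv(C, C, k = 3L, bias = TRUE, name = "path_conv")
  self$bn1 <- layer_bn(C, name = "path_bn1")
  self$relu <- layer_relu("path_relu")
  self$se <- se_unit(C, r)
  self$bn2 <- layer_bn(C, name = "path_bn2")
  self$children <- list(self$conv, self$bn1, self$relu, self$se, self$bn2)
  self$forward <- function(x, train = FALSE) {
    y <- self$conv$forward(x, train)
    y <- self$bn1$forward(y, train)
    y <- self$relu$forward(y, train)
    y <- self$se$forward(y, train)
    self$bn2$forward(y, train)
  }
  self$backward <- function(gy) {
    gy <- self$bn2$backward(gy)
    gy <- self$se$backward(gy)
    gy <- self$relu$backward(gy)
    gy <- self$bn1$backward(gy)
    self$conv$backward(gy)
  }
  self$out_shape <- function(s) s
  self$macs <- function(s) self$conv$macs(s) + self$se$macs(s)
  self
}

#' MCRT block
#'
#' Three parallel [conv_path()]s at the given excitation ratios summed with an
#' identity connection. Output shape equals input shape; with all parameters
#' zero the block is an exact identity.
#'
#' @param C Block width.
#' @param ratios Integer vector of three excitation ratios (default `c(2, 4, 8)`).
#' @return A module environment.
#' @export
mcrt_block <- function(C, ratios = c(2L, 4L, 8L)) {
  stopifnot(length(ratios) == 3L)
  self <- new_module("mcrt", sprintf("mcrt_c%d", C))
  self$C <- as.integer(C)
  self$ratios <- as.integer(ratios)
  self$paths <- lapply(self$ratios, function(r) conv_path(C, r))
  self$children <- self$paths
  self$forward <- function(x, train = FALSE) {
    x <- as_batch(x)
    if (dim(x)[3] != self$C) {
      stop(sprintf("MCRT block width %d, input has %d channels",
                   self$C, dim(x)[3]))
    }
    out <- x
    for (p in self$paths) out <- out + p$forward(x, train)
    out
  }
  self$backward <- function(gy) {
    gx <- gy
    for (p in self$paths) gx <- gx + p$backward(gy)
    gx
  }
  self$out_shape <- function(s) s
  self$macs <- function(s) sum(vapply(self$paths, function(p) p$macs(s), 0))
  self
}

## ---- spec-level operations -------------------------------------------------

#' Forward pass of a single convolution path
#'
#' @param x Feature map, `(H, W, C)` array (or `(H, W, C, N)` batch).
#' @param path A [conv_path()] module.
#' @param train Use batch statistics in the normalization layers.
#' @return Feature map of identical shape.
#' @export
conv_path_forward <- function(x, path, train = FALSE) {
  x <- as_batch(x)
  if (dim(x)[3] != path$C) {
    stop(sprintf("channel mismatch: path expects C=%d, input has C=%d",
                 path$C, dim(x)[3]))
  }
  y <- path$forward(x, train)
  if (dim(y)[4] == 1L) dim(y) <- dim(y)[1:3]
  y
}

#' Squeeze a feature map to per-channel spatial means
#'
#' @param y `(H, W, C)` feature map.
#' @return Numeric vector of length `C`; element `c` is
#'   `mean(y[ , , c])`.
#' @export
se_squeeze <- function(y) {
  stopifnot(length(dim(y)) == 3L)
  apply(y, 3L, mean)
}

#' Excitation: gate a feature map by its squeezed descriptor
#'
#' Computes `g = sigmoid(W2 %*% relu(W1 %*% s + b1) + b2)` and rescales channel
#' `c` of `y` by `g[c]`.
#'
#' @param s Channel descriptor (length-`C` vector), normally [se_squeeze()] of `y`.
#' @param unit An [se_unit()].
#' @param y `(H, W, C)` feature map to rescale.
#' @return Gated feature map, same shape as `y`.
#' @export
se_excite <- function(s, unit, y) {
  stopifnot(length(s) == dim(y)[3], length(s) == unit$C)
  g <- unit$gate(matrix(s, ncol = 1))
  sweep(y, 3L, as.numeric(g), "*")
}

#' Forward pass of an MCRT block
#'
#' @param x `(H, W, C)` feature map (or batch).
#' @param block An [mcrt_block()].
#' @param train Use batch statistics in the normalization layers.
#' @return `x + path1(x) + path2(x) + path3(x)`, same shape as `x`.
#' @export
mcrt_forward <- function(x, block, train = FALSE) {
  squeeze3 <- length(dim(x)) == 3L
  y <- block$forward(as_batch(x), train)
  if (squeeze3) dim(y) <- dim(y)[1:3]
  y
}

#' Finite-difference check of the MCRT backward pass
#'
#' Verifies the analytic input gradient (which contains the additive identity
#' term of the residual connection) against central finite differences of the
#' scalar probe `h(x) = <g, block(x)>` for a seeded random probe `g`, element
#' by element.
#'
#' @param block An [mcrt_block()].
#' @param x Small input map (at most 8x8 spatially).
#' @param eps Finite-difference step.
#' @param seed Seed for the probe direction.
#' @return Maximum absolute deviation between analytic and numeric gradient.
#' @export
mcrt_gradient_check <- function(block, x, eps = 1e-4, seed = 1L) {
  x <- as_batch(x)
  stopifnot(dim(x)[1] <= 8L, dim(x)[2] <= 8L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  probe <- array(stats::rnorm(length(x)), dim = dim(x))
  module_zero_grads(block)
  block$forward(x, train = TRUE)
  ganalytic <- block$backward(probe)
  h <- function(xx) sum(probe * block$forward(xx, train = TRUE))
  gnum <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    gnum[i] <- (h(xp) - h(xm)) / (2 * eps)
  }
  max(abs(ganalytic - gnum))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
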