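# Group Convolution Deep Localization (GCDL) head.
#
# Consumes the three stage outputs X1 (S x S x 16), X2 (S/2 x S/2 x 32),
# X3 (S/4 x S/4 x 64):
#
#   fusion:  3x3 convolutions at strides 4 / 2 / 1 bring all stages to S/4,
#            channel concatenation, then a separable (depthwise + pointwise)
#            merge convolution, BN and ReLU -> X_out (S/4 x S/4 x C_f).
#            The strided kernels are evaluated densely and decimated, which is
#            arithmetically identical to strided convolution ("pooling as well
#            as convolution") and is how their operation count is ledgered.
#   ADSC:    four depthwise-separable 3x3 branches on X_out at dilation rates
#            1, 2, 4, 6, concatenated and projected by a 1x1 convolution to 64
#            channels (BN + ReLU).
#   AM:      X_out is globally pooled; a two-layer gate (ReLU bottleneck,
#            sigmoid output, no bias on the output layer) projects the pooled
#            descriptor to 64 channels which rescale X3; BN follows.
#
# ADSC and AM outputs (both 64-channel maps at S/4) are merged by element-wise
# addition so the fixed 64-channel classifier head serves every ablation
# variant; see the methods vignette for why concatenation cannot meet the
# head's parameter ledger.

concat_channels <- function(maps) {
  d1 <- dim(maps[[1]])
  cs <- vapply(maps, function(m) dim(m)[3], 0L)
  out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (m in maps) {
    out[, , at + seq_len(dim(m)[3]), ] <- m
    at <- at + dim(m)[3]
  }
  out
}

split_channels <- function(g, cs) {
  at <- 0L
  out <- vector("list", length(cs))
  for (i in seq_along(cs)) {
    out[[i]] <- g[, , at + seq_len(cs[i]), , drop = FALSE]
    at <- at + cs[i]
  }
  out
}

#' Strided multi-scale fusion block
#'
#' @param f1,f2,f3 Output widths of the three strided 3x3 convolutions
#'   (strides 4, 2, 1 on the stage-1/2/3 maps).
#' @param cf Width of the fused descriptor after the separable merge.
#' @param in_widths Stage widths feeding the block (16, 32, 64).
#' @return A module; `$forward(x1, x2, x3)` yields X_out.
#' @export
fusion_block <- function(f1 = 9L, f2 = 11L, f3 = 15L, cf = 28L,
                         in_widths = c(16L, 32L, 64L)) {
  self <- new_module("fusion", "fusion")
  fc <- f1 + f2 + f3
  self$widths <- c(f1 = f1, f2 = f2, f3 = f3, fc = fc, cf = cf)
  self$conv1 <- layer_conv(in_widths[1], f1, stride = 4L, dense_eval = TRUE,
                           bias = TRUE, name = "fuse_conv_s4")
  self$conv2 <- layer_conv(in_widths[2], f2, stride = 2L, dense_eval = TRUE,
                           bias = TRUE, name = "fuse_conv_s2")
  self$conv3 <- layer_conv(in_widths[3], f3, stride = 1L,
                           bias = TRUE, name = "fuse_conv_s1")
  self$bn1 <- layer_bn(f1, name = "fuse_bn1")
  self$bn2 <- layer_bn(f2, name = "fuse_bn2")
  self$bn3 <- layer_bn(f3, name = "fuse_bn3")
  self$dw <- layer_conv(fc, fc, k = 3L, groups = fc, bias = FALSE,
                        name = "fuse_merge_dw")
  self$pw <- layer_conv(fc, cf, k = 1L, bias = FALSE, name = "fuse_merge_pw")
  self$bnm <- layer_bn(cf, name = "fuse_merge_bn")
  self$relu <- layer_relu("fuse_relu")
  self$children <- list(self$conv1, self$bn1, self$conv2, self$bn2,
                        self$conv3, self$bn3, self$dw, self$pw,
                        self$bnm, self$relu)

  self$forward <- function(x1, x2, x3, train = FALSE) {
    x1 <- as_batch(x1); x2 <- as_batch(x2); x3 <- as_batch(x3)
    s <- c(dim(x1)[1], dim(x2)[1], dim(x3)[1])
    if (!(s[1] == 2L * s[2] && s[2] == 2L * s[3])) {
      stop(sprintf("fusion expects spatial sizes in ratio 4:2:1, got %d / %d / %d",
                   s[1], s[2], s[3]))
    }
    y1 <- self$bn1$forward(self$conv1$forward(x1, train), train)
    y2 <- self$bn2$forward(self$conv2$forward(x2, train), train)
    y3 <- self$bn3$forward(self$conv3$forward(x3, train), train)
    self$cs <- c(dim(y1)[3], dim(y2)[3], dim(y3)[3])
    z <- concat_channels(list(y1, y2, y3))
    z <- self$dw$forward(z, train)
    z <- self$pw$forward(z, train)
    z <- self$bnm$forward(z, train)
    self$relu$forward(z, train)
  }
  self$backward <- function(gy) {
    g <- self$relu$backward(gy)
    g <- self$bnm$backward(g)
    g <- self$pw$backward(g)
    g <- self$dw$backward(g)
    gs <- split_channels(g, self$cs)
    list(gx1 = self$conv1$backward(self$bn1$backward(gs[[1]])),
         gx2 = self$conv2$backward(self$bn2$backward(gs[[2]])),
         gx3 = self$conv3$backward(self$bn3$backward(gs[[3]])))
  }
  self$macs <- function(s1) {
    # s1: (H, W, C) shape of the stage-1 map; stages 2/3 at half/quarter size
    s2 <- c(s1[1] %/% 2L, s1[2] %/% 2L, 32L)
    s3 <- c(s1[1] %/% 4L, s1[2] %/% 4L, 64L)
    self$conv1$macs(s1) + self$conv2$macs(s2) + self$conv3$macs(s3) +
      self$dw$macs(s3) + self$pw$macs(s3)
  }
  self
}

#' Aggregated depthwise-separable (dilated) block
#'
#' Four parallel depthwise-separable 3x3 convolutions at dilation rates
#' 1, 2, 4, 6 on the fused descriptor, channel-concatenated and projected to
#' `out_width` channels by a 1x1 convolution (BN + ReLU). Dilation-aware
#' 'same' padding (pad = d) keeps the block shape preserving.
#'
#' @param cf Input width (fused descriptor channels).
#' @param branch_width Output width of each dilated branch.
#' @param out_width Projection width (64, the stage-3 width).
#' @param dilations Dilation rates of the branches.
#' @return A module.
#' @export
adsc_block <- function(cf = 28L, branch_width = 27L, out_width = 64L,
                       dilations = c(1L, 2L, 4L, 6L)) {
  self <- new_module("adsc", "adsc")
  self$cf <- as.integer(cf)
  self$dilations <- as.integer(dilations)
  self$branches <- lapply(self$dilations, function(d) {
    list(dw = layer_conv(cf, cf, k = 3L, dilation = d, groups = cf,
                         bias = FALSE, name = sprintf("adsc_dw_d%d", d)),
         pw = layer_conv(cf, branch_width, k = 1L, bias = FALSE,
                         name = sprintf("adsc_pw_d%d", d)))
  })
  self$proj <- layer_conv(branch_width * length(dilations), out_width, k = 1L,
                          bias = TRUE, name = "adsc_proj")
  self$bn <- layer_bn(out_width, name = "adsc_bn")
  self$relu <- layer_relu("adsc_relu")
  self$children <- c(unlist(self$branches, recursive = FALSE),
                     list(self$proj, self$bn, self$relu))

  self$forward <- function(x, train = FALSE) {
    x <- as_batch(x)
    ys <- lapply(self$branches, function(br) {
      br$pw$forward(br$dw$forward(x, train), train)
    })
    self$cs <- vapply(ys, function(y) dim(y)[3], 0L)
    z <- concat_channels(ys)
    z <- self$proj$forward(z, train)
    z <- self$bn$forward(z, train)
    self$relu$forward(z, train)
  }
  self$backward <- function(gy) {
    g <- self$relu$backward(gy)
    g <- self$bn$backward(g)
    g <- self$proj$backward(g)
    gs <- split_channels(g, self$cs)
    gx <- 0
    for (i in seq_along(self$branches)) {
      br <- self$branches[[i]]
      gx <- gx + br$dw$backward(br$pw$backward(gs[[i]]))
    }
    gx
  }
  self$macs <- function(s) {
    per_branch <- self$branches[[1]]$dw$macs(s) + self$branches[[1]]$pw$macs(s)
    length(self$branches) * per_branch + self$proj$macs(s)
  }
  self
}

#' Global attention gate
#'
#' Globally pools the fused descriptor and projects it through a two-layer
#' gate (`cf -> hidden` with bias and ReLU, `hidden -> 64` without bias,
#' sigmoid) whose output rescales the stage-3 map channel-wise; BN follows.
#'
#' @param cf Input width (fused descriptor channels).
#' @param hidden Gate bottleneck width.
#' @param out_width Projection width (stage-3 channels, 64).
#' @return A module; `$forward(x_out, x3)`.
#' @export
attention_gate <- function(cf = 28L, hidden = 48L, out_width = 64L) {
  self <- new_module("am", "attention")
  self$cf <- as.integer(cf)
  self$fc1 <- layer_dense(cf, hidden, bias = TRUE, name = "am_fc1")
  self$fc2 <- layer_dense(hidden, out_width, bias = FALSE, name = "am_fc2")
  self$bn <- layer_bn(out_width, name = "am_bn")
  self$children <- list(self$fc1, self$fc2, self$bn)

  self$project <- function(s, train = FALSE) {
    a <- self$fc1$forward(s, train)
    self$relu_mask <- a > 0
    z <- self$fc2$forward(a * self$relu_mask, train)
    g <- 1 / (1 + exp(-z))
    self$g <- g
    g
  }
  self$project_backward <- function(gg) {
    gz <- gg * self$g * (1 - self$g)
    ga <- self$fc2$backward(gz)
    self$fc1$backward(ga * self$relu_mask)
  }
  self$forward <- function(x_out, x3, train = FALSE) {
    x_out <- as_batch(x_out); x3 <- as_batch(x3)
    if (dim(x_out)[3] != self$cf) {
      stop(sprintf("attention gate expects %d input channels, got %d",
                   self$cf, dim(x_out)[3]))
    }
    d <- dim(x_out)
    self$xout_dim <- d
    v <- x_out; dim(v) <- c(d[1] * d[2], d[3] * d[4])
    s <- matrix(colMeans(v), d[3], d[4])
    g <- self$project(s, train)
    d3 <- dim(x3)
    if (nrow(g) != d3[3]) {
      stop(sprintf("projected gate has length %d but stage-3 map has %d channels",
                   nrow(g), d3[3]))
    }
    self$x3 <- x3
    self$gexp <- array(rep(as.numeric(g), each = d3[1] * d3[2]), dim = d3)
    self$bn$forward(x3 * self$gexp, train)
  }
  self$backward <- function(gy) {
    g <- self$bn$backward(gy)
    d3 <- dim(self$x3)
    tmp <- g * self$x3
    dim(tmp) <- c(d3[1] * d3[2], d3[3] * d3[4])
    gg <- matrix(colSums(tmp), d3[3], d3[4])
    gs <- self$project_backward(gg)
    gx3 <- g * self$gexp
    d <- self$xout_dim
    gxout <- array(rep(as.numeric(gs), each = d[1] * d[2]) / (d[1] * d[2]),
                   dim = d)
    list(gx_out = gxout, gx3 = gx3)
  }
  self$macs <- function(s) self$fc1$macs(NULL) + self$fc2$macs(NULL)
  self
}

#' Assembled GCDL head
#'
#' @param cfg GCDL width configuration, see [renalnet_config()].
#' @param use_adsc,use_am Include the aggregated depthwise-separable block /
#'   the attention gate. At least one must be active.
#' @return A module; `$forward(x1, x2, x3)` yields the 64-channel localization
#'   map at stage-3 resolution, `$backward(gy)` returns gradients for the three
#'   stage inputs.
#' @export
gcdl_head <- function(cfg = renalnet_config()$gcdl, use_adsc = TRUE,
                      use_am = TRUE) {
  if (!use_adsc && !use_am) {
    stop("GCDL head needs at least one of ADSC / attention enabled")
  }
  self <- new_module("gcdl", "gcdl")
  self$fusion <- fusion_block(cfg$f1, cfg$f2, cfg$f3, cfg$cf)
  self$adsc <- if (use_adsc) adsc_block(cfg$cf, cfg$adsc_width) else NULL
  self$am <- if (use_am) attention_gate(cfg$cf, cfg$am_hidden) else NULL
  self$children <- Filter(Negate(is.null), list(self$fusion, self$adsc, self$am))

  self$forward <- function(x1, x2, x3, train = FALSE) {
    x3 <- as_batch(x3)
    x_out <- self$fusion$forward(x1, x2, x3, train)
    out <- 0
    if (!is.null(self$adsc)) out <- out + self$adsc$forward(x_out, train)
    if (!is.null(self$am)) out <- out + self$am$forward(x_out, x3, train)
    out
  }
  self$backward <- function(gy) {
    gx_out <- 0
    gx3_extra <- 0
    if (!is.null(self$adsc)) gx_out <- gx_out + self$adsc$backward(gy)
    if (!is.null(self$am)) {
      ga <- self$am$backward(gy)
      gx_out <- gx_out + ga$gx_out
      gx3_extra <- ga$gx3
    }
    gf <- self$fusion$backward(gx_out)
    list(gx1 = gf$gx1, gx2 = gf$gx2, gx3 = gf$gx3 + gx3_extra)
  }
  self$macs <- function(s1) {
    s3 <- c(s1[1] %/% 4L, s1[2] %/% 4L, self$fusion$widths[["cf"]])
    m <- self$fusion$macs(s1)
    if (!is.null(self$adsc)) m <- m + self$adsc$macs(s3)
    if (!is.null(self$am)) m <- m + self$am$macs(s3)
    m
  }
  self
}

## ---- spec-level operations -------------------------------------------------

#' Multi-scale strided fusion of three stage maps
#'
#' @param x1,x2,x3 Stage feature maps at spatial sizes in ratio 4:2:1.
#' @param cfg A [fusion_block()].
#' @param train Use batch statistics.
#' @return Fused map X_out at stage-3 resolution.
#' @export
strided_fusion <- function(x1, x2, x3, cfg, train = FALSE) {
  squeeze3 <- length(dim(x1)) == 3L
  y <- cfg$forward(as_batch(x1), as_batch(x2), as_batch(x3), train)
  if (squeeze3) dim(y) <- dim(y)[1:3]
  y
}

#' Global average pooling of a feature map
#'
#' @param x `(H, W, C)` feature map.
#' @return Numeric vector of per-channel spatial means, length `C`.
#' @export
global_pool <- function(x) {
  stopifnot(length(dim(x)) == 3L)
  apply(x, 3L, mean)
}

#' Scale a stage-3 map by an attention gate vector
#'
#' With `gate = NULL`, `gate_vec` is taken to be the already-projected
#' 64-channel gate and the map is rescaled channel-wise. With an
#' [attention_gate()] supplied, `gate_vec` is the pooled fused descriptor and
#' is projected through the gate first.
#'
#' @param gate_vec Gate vector (projected, or pooled descriptor if `gate` given).
#' @param x3 `(H, W, C)` stage-3 feature map.
#' @param gate Optional [attention_gate()] used for projection.
#' @return Rescaled map, same shape as `x3`.
#' @export
attention_scale <- function(gate_vec, x3, gate = NULL) {
  if (!is.null(gate)) {
    gate_vec <- as.numeric(gate$project(matrix(gate_vec, ncol = 1)))
  }
  if (length(gate_vec) != dim(x3)[3]) {
    stop(sprintf("gate length %d does not match %d channels of the stage-3 map",
                 length(gate_vec), dim(x3)[3]))
  }
  sweep(x3, 3L, gate_vec, "*")
}

#' Forward pass of the aggregated depthwise-separable block
#'
#' @param x_out Fused descriptor map from [strided_fusion()].
#' @param cfg An [adsc_block()].
#' @param train Use batch statistics.
#' @return Projected 64-channel map, spatial size preserved.
#' @export
adsc_forward <- function(x_out, cfg, train = FALSE) {
  squeeze3 <- length(dim(x_out)) == 3L
  y <- cfg$forward(as_batch(x_out), train)
  if (squeeze3) dim(y) <- dim(y)[1:3]
  y
}

#' Pre-classifier feature vector of the GCDL head
#'
#' Runs the fusion, ADSC and attention sub-blocks, merges their 64-channel
#' outputs and global-pools the result.
#'
#' @param x1,x2,x3 Stage feature maps.
#' @param head A [gcdl_head()].
#' @param train Use batch statistics.
#' @return Length-64 feature vector (or 64 x N matrix for batched input).
#' @export
gcdl_forward <- function(x1, x2, x3, head, train = FALSE) {
  y <- head$forward(as_batch(x1), as_batch(x2), as_batch(x3), train)
  d <- dim(y)
  dim(y) <- c(d[1] * d[2], d[3] * d[4])
  v <- matrix(colMeans(y), d[3], d[4])
  if (d[4] == 1L) as.numeric(v) else v
}
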