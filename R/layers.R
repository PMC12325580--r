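# Minimal trainable-layer framework.
#
# Every layer is an environment with a common protocol:
#   $kind, $name                  identification
#   $forward(x, train)            stores whatever the backward pass needs
#   $backward(gy)                 accumulates parameter gradients, returns gx
#   $params() / $grads()          named lists of parameter / gradient arrays
#   $set_params(p)                in-place update
#   $out_shape(s) / $macs(s)      shape propagation and multiply-accumulate
#                                 count for a (H, W, C) input shape
# Feature maps are (H, W, C, N) arrays; vector features are (C, N) matrices.
# MAC accounting follows the convention that only convolutional and fully
# connected layers count, at 1 MAC = 2 FLOPs, batch-norm/activations/pooling
# excluded.

new_module <- function(kind, name) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$name <- name
  e
}

#' @noRd
as_batch <- function(x) {
  if (length(dim(x)) == 3L) {
    dim(x) <- c(dim(x), 1L)
  }
  x
}

init_rnorm <- function(dims, sd) {
  array(stats::rnorm(prod(dims), sd = sd), dim = dims)
}

## ---- convolution -----------------------------------------------------------

# `dense_eval = TRUE` evaluates the convolution densely (stride 1) and then
# decimates rows/columns by `stride`; the result is identical to a strided
# convolution with symmetric padding, but the operation count is that of the
# dense evaluation. Used by the multi-scale fusion block, whose ledger counts
# the strided kernels at input resolution.
layer_conv <- function(cin, cout, k = 3L, stride = 1L, dilation = 1L,
                       bias = TRUE, groups = 1L, dense_eval = FALSE,
                       name = "conv") {
  stopifnot(cin %% groups == 0L, cout %% groups == 0L)
  self <- new_module("conv", name)
  self$cin <- as.integer(cin); self$cout <- as.integer(cout)
  self$k <- as.integer(k); self$stride <- as.integer(stride)
  self$dilation <- as.integer(dilation); self$groups <- as.integer(groups)
  self$use_bias <- isTRUE(bias); self$dense_eval <- isTRUE(dense_eval)
  self$pad <- if (k == 1L) 0L else as.integer(dilation)
  fan_in <- k * k * cin / groups
  self$w <- init_rnorm(c(k, k, cin %/% groups, cout), sd = sqrt(2 / fan_in))
  self$b <- if (self$use_bias) numeric(cout) else numeric(0)
  self$gw <- array(0, dim(self$w)); self$gb <- numeric(length(self$b))

  self$forward <- function(x, train = FALSE) {
    x <- as_batch(x)
    if (dim(x)[3] != self$cin) {
      stop(sprintf("layer '%s': expected %d input channels, got %d",
                   self$name, self$cin, dim(x)[3]))
    }
    self$x <- x
    s <- if (self$dense_eval) 1L else self$stride
    y <- conv2d_fw_cpp(x, dim(x), self$w, dim(self$w), self$b,
                       s, self$dilation, self$pad, self$groups)
    if (self$dense_eval && self$stride > 1L) {
      d <- dim(y)
      keep_h <- seq.int(1L, d[1], by = self$stride)
      keep_w <- seq.int(1L, d[2], by = self$stride)
      self$dense_dim <- d
      y <- y[keep_h, keep_w, , , drop = FALSE]
    }
    y
  }
  self$backward <- function(gy) {
    gy <- as_batch(gy)
    s <- if (self$dense_eval) 1L else self$stride
    if (self$dense_eval && self$stride > 1L) {
      gfull <- array(0, self$dense_dim)
      keep_h <- seq.int(1L, self$dense_dim[1], by = self$stride)
      keep_w <- seq.int(1L, self$dense_dim[2], by = self$stride)
      gfull[keep_h, keep_w, , ] <- gy
      gy <- gfull
    }
    r <- conv2d_bw_cpp(self$x, dim(self$x), self$w, dim(self$w), gy,
                       s, self$dilation, self$pad, self$groups)
    self$gw <- self$gw + r$gw
    if (self$use_bias) self$gb <- self$gb + r$gb
    r$gx
  }
  self$params <- function() {
    p <- list(w = self$w)
    if (self$use_bias) p$b <- self$b
    p
  }
  self$grads <- function() {
    g <- list(w = self$gw)
    if (self$use_bias) g$b <- self$gb
    g
  }
  self$set_params <- function(p) {
    self$w <- p$w
    if (self$use_bias) self$b <- p$b
    invisible(self)
  }
  self$out_shape <- function(s) {
    ke <- (self$k - 1L) * self$dilation + 1L
    o <- function(n) (n + 2L * self$pad - ke) %/% self$stride + 1L
    if (self$dense_eval && self$stride > 1L) {
      od <- function(n) {
        dense <- n + 2L * self$pad - ke + 1L
        length(seq.int(1L, dense, by = self$stride))
      }
      c(od(s[1]), od(s[2]), self$cout)
    } else {
      c(o(s[1]), o(s[2]), self$cout)
    }
  }
  self$macs <- function(s) {
    ke <- (self$k - 1L) * self$dilation + 1L
    if (self$dense_eval) {
      ho <- s[1] + 2L * self$pad - ke + 1L
      wo <- s[2] + 2L * self$pad - ke + 1L
    } else {
      ho <- (s[1] + 2L * self$pad - ke) %/% self$stride + 1L
      wo <- (s[2] + 2L * self$pad - ke) %/% self$stride + 1L
    }
    as.numeric(ho) * wo * self$k * self$k * (self$cin / self$groups) * self$cout
  }
  self
}

## ---- batch normalization ---------------------------------------------------

layer_bn <- function(c, momentum = 0.1, eps = 1e-5, name = "bn") {
  self <- new_module("bn", name)
  self$c <- as.integer(c)
  self$gamma <- rep(1, c); self$beta <- numeric(c)
  self$rmean <- numeric(c); self$rvar <- rep(1, c)
  self$momentum <- momentum; self$eps <- eps
  self$ggamma <- numeric(c); self$gbeta <- numeric(c)

  ch_stat <- function(x, f) {
    # per-channel statistic over (H, W, N)
    d <- dim(x)
    m <- aperm(x, c(1L, 2L, 4L, 3L))
    dim(m) <- c(d[1] * d[2] * d[4], d[3])
    f(m)
  }
  bcast <- function(v, d) {
    # channel vector -> (H, W, C, N)
    array(rep(rep(v, each = d[1] * d[2]), d[4]), dim = d)
  }
  self$forward <- function(x, train = FALSE) {
    x <- as_batch(x)
    d <- dim(x)
    if (train) {
      mu <- ch_stat(x, colMeans)
      xc <- x - bcast(mu, d)
      va <- ch_stat(xc * xc, colMeans)
      self$rmean <- (1 - self$momentum) * self$rmean + self$momentum * mu
      self$rvar <- (1 - self$momentum) * self$rvar + self$momentum * va
    } else {
      mu <- self$rmean
      va <- self$rvar
      xc <- x - bcast(mu, d)
    }
    invstd <- 1 / sqrt(va + self$eps)
    xhat <- xc * bcast(invstd, d)
    self$xhat <- xhat; self$invstd <- invstd; self$train_mode <- train
    xhat * bcast(self$gamma, d) + bcast(self$beta, d)
  }
  self$backward <- function(gy) {
    gy <- as_batch(gy)
    d <- dim(gy)
    self$ggamma <- self$ggamma + ch_stat(gy * self$xhat, colSums)
    self$gbeta <- self$gbeta + ch_stat(gy, colSums)
    gxhat <- gy * bcast(self$gamma, d)
    if (self$train_mode) {
      m <- d[1] * d[2] * d[4]
      s1 <- ch_stat(gxhat, colSums)
      s2 <- ch_stat(gxhat * self$xhat, colSums)
      (gxhat - bcast(s1 / m, d) - self$xhat * bcast(s2 / m, d)) *
        bcast(self$invstd, d)
    } else {
      gxhat * bcast(self$invstd, d)
    }
  }
  self$params <- function() list(gamma = self$gamma, beta = self$beta)
  self$grads <- function() list(gamma = self$ggamma, beta = self$gbeta)
  self$set_params <- function(p) {
    self$gamma <- p$gamma; self$beta <- p$beta
    invisible(self)
  }
  self$out_shape <- function(s) s
  self$macs <- function(s) 0
  self
}

## ---- dense (fully connected on (C, N) matrices) ----------------------------

layer_dense <- function(cin, cout, bias = TRUE, name = "fc") {
  self <- new_module("dense", name)
  self$cin <- as.integer(cin); self$cout <- as.integer(cout)
  self$use_bias <- isTRUE(bias)
  self$w <- matrix(stats::rnorm(cout * cin, sd = sqrt(2 / cin)), cout, cin)
  self$b <- if (self$use_bias) numeric(cout) else numeric(0)
  self$gw <- matrix(0, cout, cin); self$gb <- numeric(length(self$b))

  self$forward <- function(x, train = FALSE) {
    x <- as.matrix(x)
    self$x <- x
    y <- self$w %*% x
    if (self$use_bias) y <- y + self$b
    y
  }
  self$backward <- function(gy) {
    self$gw <- self$gw + gy %*% t(self$x)
    if (self$use_bias) self$gb <- self$gb + rowSums(gy)
    t(self$w) %*% gy
  }
  self$params <- function() {
    p <- list(w = self$w)
    if (self$use_bias) p$b <- self$b
    p
  }
  self$grads <- function() {
    g <- list(w = self$gw)
    if (self$use_bias) g$b <- self$gb
    g
  }
  self$set_params <- function(p) {
    self$w <- p$w
    if (self$use_bias) self$b <- p$b
    invisible(self)
  }
  self$out_shape <- function(s) self$cout
  self$macs <- function(s) as.numeric(self$cin) * self$cout
  self
}

## ---- stateless layers ------------------------------------------------------

layer_relu <- function(name = "relu") {
  self <- new_module("relu", name)
  self$forward <- function(x, train = FALSE) {
    self$mask <- x > 0
    x * self$mask
  }
  self$backward <- function(gy) gy * self$mask
  self$params <- function() list()
  self$grads <- function() list()
  self$set_params <- function(p) invisible(self)
  self$out_shape <- function(s) s
  self$macs <- function(s) 0
  self
}

layer_maxpool2 <- function(name = "pool") {
  self <- new_module("maxpool", name)
  self$forward <- function(x, train = FALSE) {
    x <- as_batch(x)
    if (dim(x)[1] %% 2L != 0L || dim(x)[2] %% 2L != 0L) {
      stop(sprintf("layer '%s': 2x2 pooling needs even spatial dims, got %dx%d",
                   self$name, dim(x)[1], dim(x)[2]))
    }
    self$xdim <- dim(x)
    r <- maxpool2_fw_cpp(x, dim(x))
    self$idx <- r$idx
    r$y
  }
  self$backward <- function(gy) maxpool2_bw_cpp(as_batch(gy), self$idx, self$xdim)
  self$params <- function() list()
  self$grads <- function() list()
  self$set_params <- function(p) invisible(self)
  self$out_shape <- function(s) c(s[1] %/% 2L, s[2] %/% 2L, s[3])
  self$macs <- function(s) 0
  self
}

# Global average pooling: (H, W, C, N) -> (C, N)
layer_gap <- function(name = "gap") {
  self <- new_module("gap", name)
  self$forward <- function(x, train = FALSE) {
    x <- as_batch(x)
    d <- dim(x)
    self$xdim <- d
    dim(x) <- c(d[1] * d[2], d[3] * d[4])
    m <- colMeans(x)
    matrix(m, d[3], d[4])
  }
  self$backward <- function(gy) {
    d <- self$xdim
    g <- array(rep(as.numeric(gy), each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
    g
  }
  self$params <- function() list()
  self$grads <- function() list()
  self$set_params <- function(p) invisible(self)
  self$out_shape <- function(s) s[3]
  self$macs <- function(s) 0
  self
}

## ---- sequential container --------------------------------------------------

seq_block <- function(layers, name = "seq") {
  self <- new_module("seq", name)
  self$layers <- layers
  self$forward <- function(x, train = FALSE) {
    for (l in self$layers) x <- l$forward(x, train)
    x
  }
  self$backward <- function(gy) {
    for (l in rev(self$layers)) gy <- l$backward(gy)
    gy
  }
  self$out_shape <- function(s) {
    for (l in self$layers) s <- l$out_shape(s)
    s
  }
  self
}

## ---- module traversal ------------------------------------------------------

# Collect leaf (parameterized or not) layers from a module tree. Composites
# expose children via $layers (list) and/or named child fields in $children.
module_leaves <- function(m) {
  if (is.null(m)) return(list())
  kids <- list()
  if (!is.null(m$layers)) kids <- c(kids, m$layers)
  if (!is.null(m$children)) kids <- c(kids, m$children)
  if (length(kids) == 0L) return(list(m))
  unlist(lapply(kids, module_leaves), recursive = FALSE)
}

# Total trainable parameters below a module.
module_param_count <- function(m) {
  sum(vapply(module_leaves(m),
             function(l) sum(vapply(l$params(), length, 0L)), 0))
}

module_zero_grads <- function(m) {
  for (l in module_leaves(m)) {
    g <- l$grads()
    if (length(g) == 0L) next
    zeroed <- lapply(g, function(a) { a[] <- 0; a })
    if (!is.null(zeroed$w)) { l$gw <- zeroed$w }
    if (!is.null(zeroed$b)) { l$gb <- zeroed$b }
    if (!is.null(zeroed$gamma)) { l$ggamma <- zeroed$gamma }
    if (!is.null(zeroed$beta)) { l$gbeta <- zeroed$beta }
  }
  invisible(m)
}

# Set every trainable parameter below `m` to zero (identity/ablation checks).
module_zero_params <- function(m) {
  for (l in module_leaves(m)) {
    p <- l$params()
    if (length(p) == 0L) next
    l$set_params(lapply(p, function(a) { a[] <- 0; a }))
  }
  invisible(m)
}

# Flat snapshot / restore of all parameters plus batch-norm running
# statistics (used for best-weight restore; the running stats belong to the
# snapshot just as the trainable weights do).
module_get_state <- function(m) {
  lapply(module_leaves(m), function(l) {
    st <- list(params = l$params())
    if (l$kind == "bn") st$running <- list(rmean = l$rmean, rvar = l$rvar)
    st
  })
}

module_set_state <- function(m, state) {
  leaves <- module_leaves(m)
  stopifnot(length(leaves) == length(state))
  for (i in seq_along(leaves)) {
    leaves[[i]]$set_params(state[[i]]$params)
    if (!is.null(state[[i]]$running)) {
      leaves[[i]]$rmean <- state[[i]]$running$rmean
      leaves[[i]]$rvar <- state[[i]]$running$rvar
    }
  }
  invisible(m)
}
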