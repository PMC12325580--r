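# Independent straight-line oracles used to cross-check the implementation.

# Triple-loop 2-D cross-correlation with symmetric zero padding; mirrors the
# layer contract (stride, dilation, groups) with no shared code.
naive_conv2d <- function(x, w, b, stride = 1L, dil = 1L, pad = 1L,
                         groups = 1L) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; N <- dim(x)[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Cg <- dim(w)[3]; Cout <- dim(w)[4]
  keh <- (kh - 1) * dil + 1; kew <- (kw - 1) * dil + 1
  Ho <- (H + 2 * pad - keh) %/% stride + 1
  Wo <- (W + 2 * pad - kew) %/% stride + 1
  cog <- Cout %/% groups
  y <- array(0, c(Ho, Wo, Cout, N))
  for (n in 1:N) for (co in 1:Cout) {
    g <- (co - 1) %/% cog
    for (ho in 1:Ho) for (wo in 1:Wo) {
      acc <- if (length(b) > 0) b[co] else 0
      for (cg in 1:Cg) {
        ci <- g * Cg + cg
        for (i in 1:kh) for (j in 1:kw) {
          hi <- (ho - 1) * stride - pad + (i - 1) * dil + 1
          wi <- (wo - 1) * stride - pad + (j - 1) * dil + 1
          if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
            acc <- acc + w[i, j, cg, co] * x[hi, wi, ci, n]
          }
        }
      }
      y[ho, wo, co, n] <- acc
    }
  }
  y
}

# Mann-Whitney pair-counting AUC (ties counted half).
pairwise_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Straight-line evaluation of the SE excitation path for one sample.
naive_se_gate <- function(s, W1, b1, W2, b2) {
  a <- as.numeric(W1 %*% s + b1)
  a[a < 0] <- 0
  1 / (1 + exp(-(as.numeric(W2 %*% a + b2))))
}
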