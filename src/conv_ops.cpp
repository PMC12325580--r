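#include <Rcpp.h>
using namespace Rcpp;

// 2-D convolution (cross-correlation) on column-major arrays.
// x: (H, W, Cin, N), w: (kh, kw, Cin/groups, Cout), b: length Cout or 0.
// Symmetric zero padding `pad`; output (Ho, Wo, Cout, N) with
// Ho = (H + 2*pad - ((kh-1)*dil + 1)) / stride + 1.
// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(NumericVector x, IntegerVector xdim,
                            NumericVector w, IntegerVector wdim,
                            NumericVector b,
                            int stride, int dil, int pad, int groups) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cg = wdim[2], Cout = wdim[3];
  const int keh = (kh - 1) * dil + 1, kew = (kw - 1) * dil + 1;
  const int Ho = (H + 2 * pad - keh) / stride + 1;
  const int Wo = (W + 2 * pad - kew) / stride + 1;
  const int cog = Cout / groups;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * Cout * N);
  const double *xp = x.begin(), *wp = w.begin();
  double *yp = y.begin();
  const bool has_b = b.size() > 0;

  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const int g = co / cog;
      double *yc = yp + (static_cast<R_xlen_t>(n) * Cout + co) * Ho * Wo;
      if (has_b) {
        const double bv = b[co];
        for (int i = 0; i < Ho * Wo; ++i) yc[i] = bv;
      }
      for (int cg = 0; cg < Cg; ++cg) {
        const int ci = g * Cg + cg;
        const double *xc = xp + (static_cast<R_xlen_t>(n) * Cin + ci) * H * W;
        const double *wc = wp + (static_cast<R_xlen_t>(co) * Cg + cg) * kh * kw;
        for (int j = 0; j < kw; ++j) {
          for (int i = 0; i < kh; ++i) {
            const double wv = wc[i + kh * j];
            if (wv == 0.0) continue;
            for (int wo = 0; wo < Wo; ++wo) {
              const int wi = wo * stride - pad + j * dil;
              if (wi < 0 || wi >= W) continue;
              const double *xcol = xc + static_cast<R_xlen_t>(wi) * H;
              double *ycol = yc + static_cast<R_xlen_t>(wo) * Ho;
              for (int ho = 0; ho < Ho; ++ho) {
                const int hi = ho * stride - pad + i * dil;
                if (hi < 0 || hi >= H) continue;
                ycol[ho] += wv * xcol[hi];
              }
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// Backward pass: returns gradients w.r.t. input, weights and bias.
// [[Rcpp::export]]
List conv2d_bw_cpp(NumericVector x, IntegerVector xdim,
                   NumericVector w, IntegerVector wdim,
                   NumericVector gy, int stride, int dil, int pad, int groups) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cg = wdim[2], Cout = wdim[3];
  const int keh = (kh - 1) * dil + 1, kew = (kw - 1) * dil + 1;
  const int Ho = (H + 2 * pad - keh) / stride + 1;
  const int Wo = (W + 2 * pad - kew) / stride + 1;
  const int cog = Cout / groups;
  NumericVector gx(static_cast<R_xlen_t>(H) * W * Cin * N);
  NumericVector gw(static_cast<R_xlen_t>(kh) * kw * Cg * Cout);
  NumericVector gb(Cout);
  const double *xp = x.begin(), *wp = w.begin(), *gyp = gy.begin();
  double *gxp = gx.begin(), *gwp = gw.begin(), *gbp = gb.begin();

  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const int g = co / cog;
      const double *gyc = gyp + (static_cast<R_xlen_t>(n) * Cout + co) * Ho * Wo;
      double acc_b = 0.0;
      for (int i = 0; i < Ho * Wo; ++i) acc_b += gyc[i];
      gbp[co] += acc_b;
      for (int cg = 0; cg < Cg; ++cg) {
        const int ci = g * Cg + cg;
        const double *xc = xp + (static_cast<R_xlen_t>(n) * Cin + ci) * H * W;
        double *gxc = gxp + (static_cast<R_xlen_t>(n) * Cin + ci) * H * W;
        const double *wc = wp + (static_cast<R_xlen_t>(co) * Cg + cg) * kh * kw;
        double *gwc = gwp + (static_cast<R_xlen_t>(co) * Cg + cg) * kh * kw;
        for (int j = 0; j < kw; ++j) {
          for (int i = 0; i < kh; ++i) {
            const double wv = wc[i + kh * j];
            double acc_w = 0.0;
            for (int wo = 0; wo < Wo; ++wo) {
              const int wi = wo * stride - pad + j * dil;
              if (wi < 0 || wi >= W) continue;
              const double *xcol = xc + static_cast<R_xlen_t>(wi) * H;
              double *gxcol = gxc + static_cast<R_xlen_t>(wi) * H;
              const double *gycol = gyc + static_cast<R_xlen_t>(wo) * Ho;
              for (int ho = 0; ho < Ho; ++ho) {
                const int hi = ho * stride - pad + i * dil;
                if (hi < 0 || hi >= H) continue;
                const double gv = gycol[ho];
                acc_w += gv * xcol[hi];
                gxcol[hi] += gv * wv;
              }
            }
            gwc[i + kh * j] += acc_w;
          }
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns pooled values and argmax indices (1-based
// into the flattened input) for the backward pass. H and W must be even.
// [[Rcpp::export]]
List maxpool2_fw_cpp(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  IntegerVector idx(y.size());
  const double *xp = x.begin();
  double *yp = y.begin();
  int *ip = idx.begin();
  R_xlen_t o = 0;
  for (int cn = 0; cn < C * N; ++cn) {
    const R_xlen_t base = static_cast<R_xlen_t>(cn) * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = 2 * ho, w0 = 2 * wo;
        R_xlen_t best = base + h0 + static_cast<R_xlen_t>(w0) * H;
        double bv = xp[best];
        const int dh[3] = {1, 0, 1}, dw[3] = {0, 1, 1};
        for (int k = 0; k < 3; ++k) {
          R_xlen_t cand = base + (h0 + dh[k]) + static_cast<R_xlen_t>(w0 + dw[k]) * H;
          if (xp[cand] > bv) { bv = xp[cand]; best = cand; }
        }
        yp[o] = bv;
        ip[o] = static_cast<int>(best) + 1;
        ++o;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw_cpp(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  NumericVector gx(static_cast<R_xlen_t>(xdim[0]) * xdim[1] * xdim[2] * xdim[3]);
  const double *gyp = gy.begin();
  const int *ip = idx.begin();
  double *gxp = gx.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) gxp[ip[i] - 1] += gyp[i];
  gx.attr("dim") = xdim;
  return gx;
}
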