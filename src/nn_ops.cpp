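// Single-pass helpers for batch normalization, coordinate-attention gating
// and directional pooling on H x W x C x N arrays. These replace chains of
// R-level aperm/reshape/broadcast operations on multi-megabyte tensors.
#include <Rcpp.h>
using namespace Rcpp;

// per-channel sum and sum of squares in one pass
// [[Rcpp::export]]
List cpp_channel_moments(NumericVector x, IntegerVector d) {
  int H = d[0], W = d[1], C = d[2], N = d[3];
  const long HW = (long)H * W;
  NumericVector s(C), s2(C);
  const double* p = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* pc = p + HW * (c + (long)C * n);
      double a = 0, b = 0;
      for (long i = 0; i < HW; ++i) { a += pc[i]; b += pc[i] * pc[i]; }
      s[c] += a; s2[c] += b;
    }
  return List::create(_["sum"] = s, _["sumsq"] = s2);
}

// y = x * a[c] + b[c]
// [[Rcpp::export]]
NumericVector cpp_channel_affine(NumericVector x, IntegerVector d,
                                 NumericVector a, NumericVector b) {
  int H = d[0], W = d[1], C = d[2], N = d[3];
  const long HW = (long)H * W;
  NumericVector y((R_xlen_t)x.size());
  y.attr("dim") = d;
  const double* p = x.begin(); double* q = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const long off = HW * (c + (long)C * n);
      const double ac = a[c], bc = b[c];
      for (long i = 0; i < HW; ++i) q[off + i] = p[off + i] * ac + bc;
    }
  return y;
}

// per-channel sum(gy) and sum(gy * xhat) in one pass
// [[Rcpp::export]]
List cpp_bn_backward_sums(NumericVector gy, NumericVector xhat,
                          IntegerVector d) {
  int H = d[0], W = d[1], C = d[2], N = d[3];
  const long HW = (long)H * W;
  NumericVector sg(C), sgx(C);
  const double* g = gy.begin(); const double* xh = xhat.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const long off = HW * (c + (long)C * n);
      double a = 0, b = 0;
      for (long i = 0; i < HW; ++i) {
        a += g[off + i]; b += g[off + i] * xh[off + i];
      }
      sg[c] += a; sgx[c] += b;
    }
  return List::create(_["sum_g"] = sg, _["sum_gx"] = sgx);
}

// gx = coef[c] * (gy - t1[c] - xhat * t2[c])
// [[Rcpp::export]]
NumericVector cpp_bn_backward_apply(NumericVector gy, NumericVector xhat,
                                    IntegerVector d, NumericVector coef,
                                    NumericVector t1, NumericVector t2) {
  int H = d[0], W = d[1], C = d[2], N = d[3];
  const long HW = (long)H * W;
  NumericVector gx((R_xlen_t)gy.size());
  gx.attr("dim") = d;
  const double* g = gy.begin(); const double* xh = xhat.begin();
  double* q = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const long off = HW * (c + (long)C * n);
      const double cc = coef[c], a = t1[c], b = t2[c];
      for (long i = 0; i < HW; ++i)
        q[off + i] = cc * (g[off + i] - a - xh[off + i] * b);
    }
  return gx;
}

// batch-norm forward in one read pass: returns both the normalized map
// xhat = (x - mu[c]) * inv_sd[c] and the output y = gamma[c]*xhat + beta[c]
// [[Rcpp::export]]
List cpp_bn_forward_pair(NumericVector x, IntegerVector d,
                         NumericVector mu, NumericVector inv_sd,
                         NumericVector gamma, NumericVector beta) {
  int H = d[0], W = d[1], C = d[2], N = d[3];
  const long HW = (long)H * W;
  NumericVector xhat((R_xlen_t)x.size()), y((R_xlen_t)x.size());
  xhat.attr("dim") = d; y.attr("dim") = d;
  const double* p = x.begin();
  double* qh = xhat.begin(); double* qy = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const long off = HW * (c + (long)C * n);
      const double m = mu[c], s = inv_sd[c], g = gamma[c], b = beta[c];
      for (long i = 0; i < HW; ++i) {
        const double h = (p[off + i] - m) * s;
        qh[off + i] = h;
        qy[off + i] = g * h + b;
      }
    }
  return List::create(_["xhat"] = xhat, _["y"] = y);
}

// [[Rcpp::export]]
NumericVector cpp_relu_forward(NumericVector x) {
  NumericVector y((R_xlen_t)x.size());
  y.attr("dim") = x.attr("dim");
  const double* p = x.begin(); double* q = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) q[i] = p[i] > 0 ? p[i] : 0;
  return y;
}

// backward using the cached output (y > 0 iff x > 0)
// [[Rcpp::export]]
NumericVector cpp_relu_backward(NumericVector gy, NumericVector y) {
  NumericVector gx((R_xlen_t)gy.size());
  gx.attr("dim") = gy.attr("dim");
  const double* g = gy.begin(); const double* p = y.begin();
  double* q = gx.begin();
  const R_xlen_t n = gy.size();
  for (R_xlen_t i = 0; i < n; ++i) q[i] = p[i] > 0 ? g[i] : 0;
  return gx;
}

// constant-pad spatial dims by p with a per-channel value
// [[Rcpp::export]]
NumericVector cpp_pad_spatial(NumericVector x, IntegerVector d, int p,
                              NumericVector value) {
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int HP = H + 2 * p, WP = W + 2 * p;
  NumericVector out((R_xlen_t)HP * WP * C * N);
  out.attr("dim") = IntegerVector::create(HP, WP, C, N);
  const double* src = x.begin();
  double* q = out.begin();
  const bool per_ch = value.size() > 1;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double v = per_ch ? value[c] : value[0];
      double* qc = q + (long)HP * WP * (c + (long)C * n);
      const double* sc = src + (long)H * W * (c + (long)C * n);
      for (long i = 0; i < (long)HP * WP; ++i) qc[i] = v;
      for (int w = 0; w < W; ++w)
        memcpy(qc + (long)(w + p) * HP + p, sc + (long)w * H,
               (size_t)H * sizeof(double));
    }
  return out;
}

// directional average pooling: zh[h,c,n] = mean_w x, zw[w,c,n] = mean_h x
// [[Rcpp::export]]
List cpp_dir_pool(NumericVector x, IntegerVector d) {
  int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector zh((R_xlen_t)H * C * N), zw((R_xlen_t)W * C * N);
  zh.attr("dim") = IntegerVector::create(H, C, N);
  zw.attr("dim") = IntegerVector::create(W, C, N);
  const double* p = x.begin();
  double* ph = zh.begin(); double* pw = zw.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* pc = p + (long)H * W * (c + (long)C * n);
      double* zhc = ph + (long)H * (c + (long)C * n);
      double* zwc = pw + (long)W * (c + (long)C * n);
      for (int w = 0; w < W; ++w) {
        const double* col = pc + (long)w * H;
        double s = 0;
        for (int h = 0; h < H; ++h) { s += col[h]; zhc[h] += col[h]; }
        zwc[w] = s / H;
      }
      for (int h = 0; h < H; ++h) zhc[h] /= W;
    }
  return List::create(_["z_h"] = zh, _["z_w"] = zw);
}

// y = x * gh[h,c,n] * gw[w,c,n]
// [[Rcpp::export]]
NumericVector cpp_gate_apply(NumericVector x, IntegerVector d,
                             NumericVector gh, NumericVector gw) {
  int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector y((R_xlen_t)x.size());
  y.attr("dim") = d;
  const double* p = x.begin(); double* q = y.begin();
  const double* ph = gh.begin(); const double* pw = gw.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const long off = (long)H * W * (c + (long)C * n);
      const double* ghc = ph + (long)H * (c + (long)C * n);
      const double* gwc = pw + (long)W * (c + (long)C * n);
      for (int w = 0; w < W; ++w) {
        const double gwv = gwc[w];
        const double* pc = p + off + (long)w * H;
        double* qc = q + off + (long)w * H;
        for (int h = 0; h < H; ++h) qc[h] = pc[h] * ghc[h] * gwv;
      }
    }
  return y;
}

// backward of the gate product: gx = gy*gh*gw, dgh = sum_w gy*x*gw,
// dgw = sum_h gy*x*gh, all in one pass
// [[Rcpp::export]]
List cpp_gate_backward(NumericVector gy, NumericVector x, IntegerVector d,
                       NumericVector gh, NumericVector gw) {
  int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector gx((R_xlen_t)x.size());
  gx.attr("dim") = d;
  NumericVector dgh((R_xlen_t)H * C * N), dgw((R_xlen_t)W * C * N);
  dgh.attr("dim") = IntegerVector::create(H, C, N);
  dgw.attr("dim") = IntegerVector::create(W, C, N);
  const double* g = gy.begin(); const double* p = x.begin();
  const double* ph = gh.begin(); const double* pw = gw.begin();
  double* qx = gx.begin(); double* qh = dgh.begin(); double* qw = dgw.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const long off = (long)H * W * (c + (long)C * n);
      const double* ghc = ph + (long)H * (c + (long)C * n);
      const double* gwc = pw + (long)W * (c + (long)C * n);
      double* dhc = qh + (long)H * (c + (long)C * n);
      double* dwc = qw + (long)W * (c + (long)C * n);
      for (int w = 0; w < W; ++w) {
        const double gwv = gwc[w];
        const double* gc = g + off + (long)w * H;
        const double* pc = p + off + (long)w * H;
        double* qc = qx + off + (long)w * H;
        double sw = 0;
        for (int h = 0; h < H; ++h) {
          const double gxp = gc[h] * pc[h];
          qc[h] = gc[h] * ghc[h] * gwv;
          dhc[h] += gxp * gwv;
          sw += gxp * ghc[h];
        }
        dwc[w] = sw;
      }
    }
  return List::create(_["gx"] = gx, _["dgh"] = dgh, _["dgw"] = dgw);
}

// add the directional-pool backward contribution in place:
// gx[h,w,c,n] += dzh[h,c,n]/W + dzw[w,c,n]/H
// [[Rcpp::export]]
NumericVector cpp_dir_pool_backward_add(NumericVector gx, IntegerVector d,
                                        NumericVector dzh, NumericVector dzw) {
  int H = d[0], W = d[1], C = d[2], N = d[3];
  double* q = gx.begin();
  const double* ph = dzh.begin(); const double* pw = dzw.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const long off = (long)H * W * (c + (long)C * n);
      const double* dhc = ph + (long)H * (c + (long)C * n);
      const double* dwc = pw + (long)W * (c + (long)C * n);
      for (int w = 0; w < W; ++w) {
        const double add_w = dwc[w] / H;
        double* qc = q + off + (long)w * H;
        for (int h = 0; h < H; ++h) qc[h] += dhc[h] / W + add_w;
      }
    }
  return gx;
}
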