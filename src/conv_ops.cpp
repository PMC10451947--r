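// Dense 2-D convolution kernels (cross-correlation convention) used by all
// network layers. Tensors are R arrays in H x W x C x N layout (column-major,
// H fastest); weights are K x K x Cin x Cout. Implementation: im2col into a
// (OH*OW*N) x (K*K*Cin) matrix whose columns are filled with contiguous
// copies, then one BLAS GEMM. The kernels are templated on the element type:
// the default path is double precision; a single-precision path (used by the
// training loop, where gradient arithmetic does not need double) halves the
// memory traffic and doubles the GEMM rate.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void out_dims(int H, int W, int K, int stride, int pad, int& OH, int& OW) {
  OH = (H + 2 * pad - K) / stride + 1;
  OW = (W + 2 * pad - K) / stride + 1;
  if (OH < 1 || OW < 1) stop("convolution output has empty spatial extent");
}

// colT(p, r): p = oh + OH*(ow + OW*n), r = kh + K*(kw + K*c).
// For stride 1 each (n, ow, c, kw, kh) slot is a contiguous run over oh.
template <typename eT, typename srcT>
static arma::Mat<eT> im2colT(const srcT* x, int H, int W, int C, int N,
                             int K, int stride, int pad, int OH, int OW) {
  arma::Mat<eT> colT((arma::uword)OH * OW * N, (arma::uword)K * K * C);
  if (pad > 0) colT.zeros();  // only border cells stay zero
  const long HW = (long)H * W;
  const long OHOW = (long)OH * OW;
  for (int c = 0; c < C; ++c)
    for (int kw = 0; kw < K; ++kw)
      for (int kh = 0; kh < K; ++kh) {
        eT* dst0 = colT.colptr((arma::uword)kh + K * (kw + (arma::uword)K * c));
        for (int n = 0; n < N; ++n) {
          const srcT* xc = x + (long)n * HW * C + (long)c * HW;
          for (int ow = 0; ow < OW; ++ow) {
            int iw = ow * stride - pad + kw;
            if (iw < 0 || iw >= W) continue;
            eT* dst = dst0 + (long)n * OHOW + (long)ow * OH;
            const srcT* src = xc + (long)iw * H;
            // valid oh range: 0 <= oh*stride - pad + kh < H
            int lo = 0, hi = OH - 1;
            while (lo * stride - pad + kh < 0) ++lo;
            while (hi * stride - pad + kh >= H) --hi;
            const srcT* s2 = src - pad + kh;
            for (int oh = lo; oh <= hi; ++oh)
              dst[oh] = (eT)s2[(long)oh * stride];
          }
        }
      }
  return colT;
}

// scatter-add colT back into an input-shaped array (gradient of im2col)
template <typename eT>
static void col2im_add(const arma::Mat<eT>& colT, double* gx,
                       int H, int W, int C, int N,
                       int K, int stride, int pad, int OH, int OW) {
  const long HW = (long)H * W;
  const long OHOW = (long)OH * OW;
  for (int c = 0; c < C; ++c)
    for (int kw = 0; kw < K; ++kw)
      for (int kh = 0; kh < K; ++kh) {
        const eT* src0 =
          colT.colptr((arma::uword)kh + K * (kw + (arma::uword)K * c));
        for (int n = 0; n < N; ++n) {
          double* xc = gx + (long)n * HW * C + (long)c * HW;
          for (int ow = 0; ow < OW; ++ow) {
            int iw = ow * stride - pad + kw;
            if (iw < 0 || iw >= W) continue;
            const eT* src = src0 + (long)n * OHOW + (long)ow * OH;
            double* dst = xc + (long)iw * H;
            int lo = 0, hi = OH - 1;
            while (lo * stride - pad + kh < 0) ++lo;
            while (hi * stride - pad + kh >= H) --hi;
            double* d2 = dst - pad + kh;
            for (int oh = lo; oh <= hi; ++oh)
              d2[(long)oh * stride] += (double)src[oh];
          }
        }
      }
}

// reshape gy (OH, OW, Cout, N) into G(p, co), p = oh + OH*(ow + OW*n)
template <typename eT>
static arma::Mat<eT> gy_to_G(const double* gy, int OH, int OW, int Cout, int N) {
  arma::Mat<eT> G((arma::uword)OH * OW * N, Cout);
  const long OHOW = (long)OH * OW;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      eT* dst = G.colptr(co) + (long)n * OHOW;
      const double* src = gy + OHOW * (co + (long)Cout * n);
      for (long p = 0; p < OHOW; ++p) dst[p] = (eT)src[p];
    }
  return G;
}

template <typename eT>
static arma::Mat<eT> w_to_mat(const double* w, long nr, int nc) {
  arma::Mat<eT> wm((arma::uword)nr, (arma::uword)nc);
  for (long j = 0; j < nc; ++j)
    for (long i = 0; i < nr; ++i) wm(i, j) = (eT)w[i + nr * j];
  return wm;
}

template <typename eT>
static NumericVector conv_forward_t(const double* x, int H, int W, int C, int N,
                                    const double* w, int K, int Cout,
                                    const double* bias, bool has_b,
                                    int stride, int pad, int OH, int OW) {
  arma::Mat<eT> colT = im2colT<eT>(x, H, W, C, N, K, stride, pad, OH, OW);
  arma::Mat<eT> wm = w_to_mat<eT>(w, (long)K * K * C, Cout);
  arma::Mat<eT> y = colT * wm;  // (OH*OW*N) x Cout
  NumericVector out((R_xlen_t)OH * OW * Cout * N);
  out.attr("dim") = IntegerVector::create(OH, OW, Cout, N);
  double* o = out.begin();
  const long OHOW = (long)OH * OW;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const eT* yc = y.colptr(co) + (long)n * OHOW;
      double* oc = o + OHOW * (co + (long)Cout * n);
      const double b = has_b ? bias[co] : 0.0;
      for (long p = 0; p < OHOW; ++p) oc[p] = (double)yc[p] + b;
    }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, IntegerVector xdim,
                                 NumericVector w, IntegerVector wdim,
                                 NumericVector bias, int stride, int pad,
                                 bool fast = false) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int K = wdim[0], Cin = wdim[2], Cout = wdim[3];
  if (wdim[1] != K) stop("non-square kernel");
  if (Cin != C) stop("input channel mismatch: x has %d, kernel expects %d", C, Cin);
  int OH, OW; out_dims(H, W, K, stride, pad, OH, OW);
  if (fast)
    return conv_forward_t<float>(x.begin(), H, W, C, N, w.begin(), K, Cout,
                                 bias.begin(), bias.size() > 0, stride, pad,
                                 OH, OW);
  return conv_forward_t<double>(x.begin(), H, W, C, N, w.begin(), K, Cout,
                                bias.begin(), bias.size() > 0, stride, pad,
                                OH, OW);
}

template <typename eT>
static void conv_backward_t(List& out,
                            const double* x, int H, int W, int C, int N,
                            const double* w, int K, int Cout,
                            const double* gy, int OH, int OW,
                            int stride, int pad, bool want_gx, bool want_gw,
                            IntegerVector xdim, IntegerVector wdim) {
  arma::Mat<eT> G = gy_to_G<eT>(gy, OH, OW, Cout, N);
  if (want_gw) {
    arma::Mat<eT> colT = im2colT<eT>(x, H, W, C, N, K, stride, pad, OH, OW);
    arma::Mat<eT> gw = colT.t() * G;  // (K*K*C) x Cout
    NumericVector gwv((R_xlen_t)gw.n_elem);
    for (arma::uword i = 0; i < gw.n_elem; ++i) gwv[i] = (double)gw(i);
    gwv.attr("dim") = wdim;
    arma::Row<eT> gb = arma::sum(G, 0);
    NumericVector gbv(Cout);
    for (int i = 0; i < Cout; ++i) gbv[i] = (double)gb(i);
    out["gw"] = gwv;
    out["gb"] = gbv;
  }
  if (want_gx) {
    arma::Mat<eT> wm = w_to_mat<eT>(w, (long)K * K * C, Cout);
    arma::Mat<eT> gcolT = G * wm.t();  // (OH*OW*N) x (K*K*C)
    NumericVector gx((R_xlen_t)H * W * C * N);
    gx.attr("dim") = xdim;
    col2im_add<eT>(gcolT, gx.begin(), H, W, C, N, K, stride, pad, OH, OW);
    out["gx"] = gx;
  }
}

// Full backward pass: builds the column matrix once and returns the
// gradients with respect to input, weights and bias.
// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, IntegerVector xdim,
                         NumericVector w, IntegerVector wdim,
                         NumericVector gy, IntegerVector gydim,
                         int stride, int pad, bool want_gx, bool want_gw,
                         bool fast = false) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int K = wdim[0], Cout = wdim[3];
  int OH = gydim[0], OW = gydim[1];
  List out;
  if (fast)
    conv_backward_t<float>(out, x.begin(), H, W, C, N, w.begin(), K, Cout,
                           gy.begin(), OH, OW, stride, pad, want_gx, want_gw,
                           xdim, wdim);
  else
    conv_backward_t<double>(out, x.begin(), H, W, C, N, w.begin(), K, Cout,
                            gy.begin(), OH, OW, stride, pad, want_gx, want_gw,
                            xdim, wdim);
  return out;
}

// K x K average pooling, stride 1, valid (input already padded): the cheap
// direct path for the DBB average branch (per-channel, no GEMM needed)
// [[Rcpp::export]]
NumericVector cpp_avgpool_s1_valid(NumericVector x, IntegerVector xdim, int K) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int OH = H - K + 1, OW = W - K + 1;
  if (OH < 1 || OW < 1) stop("avgpool output has empty spatial extent");
  NumericVector out((R_xlen_t)OH * OW * C * N);
  out.attr("dim") = IntegerVector::create(OH, OW, C, N);
  const double inv = 1.0 / (K * K);
  const double* p = x.begin();
  double* q = out.begin();
  std::vector<double> colsum((size_t)H);
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* pc = p + (long)H * W * cn;
    double* qc = q + (long)OH * OW * cn;
    for (int ow = 0; ow < OW; ++ow) {
      for (int h = 0; h < H; ++h) colsum[h] = 0;
      for (int kw = 0; kw < K; ++kw) {
        const double* col = pc + (long)(ow + kw) * H;
        for (int h = 0; h < H; ++h) colsum[h] += col[h];
      }
      double* qcol = qc + (long)ow * OH;
      for (int oh = 0; oh < OH; ++oh) {
        double s = 0;
        for (int kh = 0; kh < K; ++kh) s += colsum[oh + kh];
        qcol[oh] = s * inv;
      }
    }
  }
  return out;
}

// backward of the above: spread each gy cell uniformly over its window
// [[Rcpp::export]]
NumericVector cpp_avgpool_s1_valid_backward(NumericVector gy,
                                            IntegerVector gydim,
                                            IntegerVector xdim, int K) {
  int OH = gydim[0], OW = gydim[1];
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = xdim;
  const double inv = 1.0 / (K * K);
  const double* g = gy.begin();
  double* q = gx.begin();
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* gc = g + (long)OH * OW * cn;
    double* qc = q + (long)H * W * cn;
    for (int ow = 0; ow < OW; ++ow)
      for (int kw = 0; kw < K; ++kw) {
        double* qcol = qc + (long)(ow + kw) * H;
        const double* gcol = gc + (long)ow * OH;
        for (int oh = 0; oh < OH; ++oh)
          for (int kh = 0; kh < K; ++kh)
            qcol[oh + kh] += gcol[oh] * inv;
      }
  }
  return gx;
}
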