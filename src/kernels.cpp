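// Hot numeric kernels for the MobileViT layers: column broadcasts used by
// the normalization layers, SiLU, depthwise 3x3 convolution, and
// im2col/col2im for the standard convolutions. Activation arrays are
// column-major with layout (H, W, N, C); channel matrices are (H*W*N, C).

#include <Rcpp.h>
using namespace Rcpp;

// y[i, c] = x[i, c] * g[c] + b[c]
// [[Rcpp::export]]
NumericMatrix cpp_col_scale_shift(const NumericMatrix& x,
                                  const NumericVector& g,
                                  const NumericVector& b) {
  const int n = x.nrow(), C = x.ncol();
  NumericMatrix y(n, C);
  for (int c = 0; c < C; ++c) {
    const double gc = g[c], bc = b[c];
    const double* xs = &x(0, c);
    double* ys = &y(0, c);
    for (int i = 0; i < n; ++i) ys[i] = xs[i] * gc + bc;
  }
  return y;
}

// y[i, c] = x[i, c] * v[c]
// [[Rcpp::export]]
NumericMatrix cpp_col_scale(const NumericMatrix& x, const NumericVector& v) {
  const int n = x.nrow(), C = x.ncol();
  NumericMatrix y(n, C);
  for (int c = 0; c < C; ++c) {
    const double vc = v[c];
    const double* xs = &x(0, c);
    double* ys = &y(0, c);
    for (int i = 0; i < n; ++i) ys[i] = xs[i] * vc;
  }
  return y;
}

// batch-norm backward core:
// dx[i, c] = (dxhat[i, c] - m1[c] - xhat[i, c] * m2[c]) * invstd[c]
// [[Rcpp::export]]
NumericMatrix cpp_bn_bwd(const NumericMatrix& dxhat,
                         const NumericMatrix& xhat,
                         const NumericVector& m1, const NumericVector& m2,
                         const NumericVector& invstd) {
  const int n = dxhat.nrow(), C = dxhat.ncol();
  NumericMatrix dx(n, C);
  for (int c = 0; c < C; ++c) {
    const double a = m1[c], b = m2[c], s = invstd[c];
    const double* dh = &dxhat(0, c);
    const double* xh = &xhat(0, c);
    double* d = &dx(0, c);
    for (int i = 0; i < n; ++i) d[i] = (dh[i] - a - xh[i] * b) * s;
  }
  return dx;
}

// colSums(a * b) without materializing the product
// [[Rcpp::export]]
NumericVector cpp_colsums_prod(const NumericMatrix& a,
                               const NumericMatrix& b) {
  const int n = a.nrow(), C = a.ncol();
  NumericVector out(C);
  for (int c = 0; c < C; ++c) {
    const double* as = &a(0, c);
    const double* bs = &b(0, c);
    double acc = 0.0;
    for (int i = 0; i < n; ++i) acc += as[i] * bs[i];
    out[c] = acc;
  }
  return out;
}

// SiLU forward: returns list(out = x * sigmoid(x), s = sigmoid(x))
// [[Rcpp::export]]
List cpp_silu_fwd(const NumericVector& x) {
  const R_xlen_t n = x.size();
  NumericVector y(n), s(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double si = 1.0 / (1.0 + std::exp(-x[i]));
    s[i] = si;
    y[i] = x[i] * si;
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["out"] = y, _["s"] = s);
}

// SiLU backward: dout * s * (1 + x * (1 - s))
// [[Rcpp::export]]
NumericVector cpp_silu_bwd(const NumericVector& dout,
                           const NumericVector& x, const NumericVector& s) {
  const R_xlen_t n = dout.size();
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i)
    d[i] = dout[i] * (s[i] * (1.0 + x[i] * (1.0 - s[i])));
  d.attr("dim") = dout.attr("dim");
  return d;
}

static inline R_xlen_t idx4(int h, int w, int n, int c, int H, int W, int N) {
  return h + (R_xlen_t)H * (w + (R_xlen_t)W * (n + (R_xlen_t)N * c));
}

// depthwise 3x3 convolution on a padded array xp (Hp, Wp, N, C);
// W9 is 9 x C (taps t = di + 3*dj); output (Ho, Wo, N, C)
// [[Rcpp::export]]
NumericVector cpp_dwconv_fwd(const NumericVector& xp, const NumericMatrix& W9,
                             int Hp, int Wp, int N, int C,
                             int Ho, int Wo, int stride) {
  NumericVector out((R_xlen_t)Ho * Wo * N * C);
  const double* xs = xp.begin();
  double* os = out.begin();
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int wo = 0; wo < Wo; ++wo) {
        const int wi = wo * stride;
        for (int ho = 0; ho < Ho; ++ho) {
          const int hi = ho * stride;
          double acc = 0.0;
          for (int dj = 0; dj < 3; ++dj)
            for (int di = 0; di < 3; ++di)
              acc += W9(di + 3 * dj, c) *
                xs[idx4(hi + di, wi + dj, n, c, Hp, Wp, N)];
          os[idx4(ho, wo, n, c, Ho, Wo, N)] = acc;
        }
      }
  out.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  return out;
}

// depthwise 3x3 backward: returns list(dxp, dW)
// [[Rcpp::export]]
List cpp_dwconv_bwd(const NumericVector& xp, const NumericVector& dout,
                    const NumericMatrix& W9, int Hp, int Wp, int N, int C,
                    int Ho, int Wo, int stride) {
  NumericVector dxp((R_xlen_t)Hp * Wp * N * C);
  NumericMatrix dW(9, C);
  const double* xs = xp.begin();
  const double* ds = dout.begin();
  double* dxs = dxp.begin();
  for (int c = 0; c < C; ++c) {
    double dw[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
    for (int n = 0; n < N; ++n)
      for (int wo = 0; wo < Wo; ++wo) {
        const int wi = wo * stride;
        for (int ho = 0; ho < Ho; ++ho) {
          const int hi = ho * stride;
          const double g = ds[idx4(ho, wo, n, c, Ho, Wo, N)];
          for (int dj = 0; dj < 3; ++dj)
            for (int di = 0; di < 3; ++di) {
              const R_xlen_t k = idx4(hi + di, wi + dj, n, c, Hp, Wp, N);
              dw[di + 3 * dj] += g * xs[k];
              dxs[k] += g * W9(di + 3 * dj, c);
            }
        }
      }
    for (int t = 0; t < 9; ++t) dW(t, c) = dw[t];
  }
  dxp.attr("dim") = IntegerVector::create(Hp, Wp, N, C);
  return List::create(_["dxp"] = dxp, _["dW"] = dW);
}

// im2col: padded (Hp, Wp, N, C) -> (Ho*Wo*N, k*k*C); column (t, c) holds
// tap t = di + k*dj of channel c, rows ordered (ho, wo, n)
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericVector& xp, int Hp, int Wp, int N,
                         int C, int k, int Ho, int Wo, int stride) {
  NumericMatrix cols((R_xlen_t)Ho * Wo * N, (R_xlen_t)k * k * C);
  const double* xs = xp.begin();
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        const int t = di + k * dj;
        double* col = &cols(0, (R_xlen_t)t * C + c);
        for (int n = 0; n < N; ++n)
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride + dj;
            const double* src =
              xs + idx4(di, wi, n, c, Hp, Wp, N);
            double* dst = col + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
            for (int ho = 0; ho < Ho; ++ho) dst[ho] = src[ho * stride];
          }
      }
  return cols;
}

// col2im: accumulate (Ho*Wo*N, k*k*C) gradients back into (Hp, Wp, N, C)
// [[Rcpp::export]]
NumericVector cpp_col2im(const NumericMatrix& dcols, int Hp, int Wp, int N,
                         int C, int k, int Ho, int Wo, int stride) {
  NumericVector dxp((R_xlen_t)Hp * Wp * N * C);
  double* dxs = dxp.begin();
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        const int t = di + k * dj;
        const double* col = &dcols(0, (R_xlen_t)t * C + c);
        for (int n = 0; n < N; ++n)
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride + dj;
            double* dst = dxs + idx4(di, wi, n, c, Hp, Wp, N);
            const double* src = col + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
            for (int ho = 0; ho < Ho; ++ho) dst[ho * stride] += src[ho];
          }
      }
  dxp.attr("dim") = IntegerVector::create(Hp, Wp, N, C);
  return dxp;
}
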