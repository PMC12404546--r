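// Minimal conv-net primitives (single precision, CPU).
// Array layout follows R column-major convention: x[H, W, C, N].
//
// Convolutions use a gather-based im2col: a position->source index map is
// built once per call and reused for every image in the batch, the patch
// matrix for the whole batch is assembled as one (N*P) x (k*k*Cin) matrix
// and multiplied in a single sgemm. im2col feature columns are ordered
// (kh, kw, cin), matching the R flattening of a [k, k, Cin, Cout] weight
// array, so matrix(w, k*k*Cin) on the R side and the reshape here agree.
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::fvec as_fvec(const NumericVector& x) {
  arma::fvec out(x.size());
  const double* p = x.begin();
  for (arma::uword i = 0; i < out.n_elem; ++i) out[i] = (float)p[i];
  return out;
}

// idx[p + P*j] = linear index into one image's [H, W, C] block for output
// position p and feature j = kh + k*kw + k*k*c, or -1 for zero padding.
static std::vector<long long> conv_index_map(int H, int W, int C, int k, int stride,
                                 int pad, int OH, int OW) {
  const int P = OH * OW, kkc = k * k * C;
  std::vector<long long> idx((size_t)P * kkc);
  for (int c = 0; c < C; ++c)
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        const int j = kh + k * kw + k * k * c;
        long long* col = idx.data() + (size_t)P * j;
        for (int ow = 0; ow < OW; ++ow) {
          const int wi = ow * stride - pad + kw;
          const bool wok = (wi >= 0 && wi < W);
          for (int oh = 0; oh < OH; ++oh) {
            const int hi = oh * stride - pad + kh;
            col[oh + OH * ow] = (wok && hi >= 0 && hi < H)
              ? (long long)(hi + (size_t)H * wi + (size_t)H * W * c) : -1;
          }
        }
      }
  return idx;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, int k, int cin, int cout,
                             NumericVector b, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  if (C != cin) stop("input channel mismatch: got %d, weights expect %d", C, cin);
  const int OH = (H + 2 * pad - k) / stride + 1;
  const int OW = (W + 2 * pad - k) / stride + 1;
  if (OH < 1 || OW < 1) stop("kernel larger than padded input");
  const int P = OH * OW, kkc = k * k * cin;
  const size_t img = (size_t)H * W * C;

  arma::fvec xf = as_fvec(x);
  arma::fmat Wf(kkc, cout);
  { arma::fvec wf = as_fvec(w); std::copy(wf.begin(), wf.end(), Wf.begin()); }
  arma::frowvec bf(cout);
  for (int i = 0; i < cout; ++i) bf[i] = (float)b[i];

  std::vector<long long> idx = conv_index_map(H, W, C, k, stride, pad, OH, OW);
  // chunk the batch so the patch matrix stays modest (cache-friendly for
  // many small images, bounded memory for few large ones)
  const int chunk = std::max(1, (int)(8000000 / ((size_t)P * kkc)));
  arma::fmat A((size_t)std::min(N, chunk) * P, kkc);
  NumericVector y((size_t)P * cout * N);
  double* yp = y.begin();
  for (int n0 = 0; n0 < N; n0 += chunk) {
    const int g = std::min(chunk, N - n0);
    if ((int)(A.n_rows) != g * P) A.set_size((size_t)g * P, kkc);
    for (int j = 0; j < kkc; ++j) {
      const long long* ic = idx.data() + (size_t)P * j;
      float* ac = A.colptr(j);
      for (int n = 0; n < g; ++n) {
        const float* xi = xf.memptr() + img * (n0 + n);
        float* an = ac + (size_t)P * n;
        for (int p = 0; p < P; ++p) an[p] = ic[p] >= 0 ? xi[ic[p]] : 0.0f;
      }
    }
    arma::fmat Y = A * Wf;          // (g*P) x cout
    Y.each_row() += bf;
    // y[oh, ow, co, n]: per-image block is P x cout, Y rows are (n, p)
    for (int co = 0; co < cout; ++co) {
      const float* yc = Y.colptr(co);
      for (int n = 0; n < g; ++n) {
        double* dst = yp + (size_t)P * (co + (size_t)cout * (n0 + n));
        const float* src = yc + (size_t)P * n;
        for (int p = 0; p < P; ++p) dst[p] = (double)src[p];
      }
    }
  }
  y.attr("dim") = IntegerVector::create(OH, OW, cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, IntegerVector xdim,
                    NumericVector w, int k, int cin, int cout,
                    NumericVector gy, int stride, int pad, bool need_gx) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int OH = (H + 2 * pad - k) / stride + 1;
  const int OW = (W + 2 * pad - k) / stride + 1;
  const int P = OH * OW, kkc = k * k * cin;
  const size_t img = (size_t)H * W * C;

  arma::fvec xf = as_fvec(x);
  arma::fmat Wf(kkc, cout);
  { arma::fvec wf = as_fvec(w); std::copy(wf.begin(), wf.end(), Wf.begin()); }

  std::vector<long long> idx = conv_index_map(H, W, C, k, stride, pad, OH, OW);
  const int chunk = std::max(1, (int)(8000000 / ((size_t)P * kkc)));
  arma::fmat A((size_t)std::min(N, chunk) * P, kkc);
  arma::fmat G((size_t)std::min(N, chunk) * P, cout);
  arma::fmat GW(kkc, cout, arma::fill::zeros);
  arma::frowvec GB(cout, arma::fill::zeros);
  arma::fvec GX;
  if (need_gx) GX.zeros(xf.n_elem);
  const double* gp = gy.begin();

  for (int n0 = 0; n0 < N; n0 += chunk) {
    const int g = std::min(chunk, N - n0);
    if ((int)(A.n_rows) != g * P) {
      A.set_size((size_t)g * P, kkc);
      G.set_size((size_t)g * P, cout);
    }
    // G rows ordered (n, p) to match the patch matrix rows
    for (int co = 0; co < cout; ++co) {
      float* gc = G.colptr(co);
      for (int n = 0; n < g; ++n) {
        const double* src = gp + (size_t)P * (co + (size_t)cout * (n0 + n));
        float* dst = gc + (size_t)P * n;
        for (int p = 0; p < P; ++p) dst[p] = (float)src[p];
      }
    }
    for (int j = 0; j < kkc; ++j) {
      const long long* ic = idx.data() + (size_t)P * j;
      float* ac = A.colptr(j);
      for (int n = 0; n < g; ++n) {
        const float* xi = xf.memptr() + img * (n0 + n);
        float* an = ac + (size_t)P * n;
        for (int p = 0; p < P; ++p) an[p] = ic[p] >= 0 ? xi[ic[p]] : 0.0f;
      }
    }
    GW += A.t() * G;
    GB += arma::sum(G, 0);
    if (need_gx) {
      arma::fmat GA = G * Wf.t();   // (g*P) x kkc
      for (int j = 0; j < kkc; ++j) {
        const long long* ic = idx.data() + (size_t)P * j;
        const float* gc = GA.colptr(j);
        for (int n = 0; n < g; ++n) {
          float* gxi = GX.memptr() + img * (n0 + n);
          const float* gn = gc + (size_t)P * n;
          for (int p = 0; p < P; ++p) if (ic[p] >= 0) gxi[ic[p]] += gn[p];
        }
      }
    }
  }

  NumericVector gw(GW.n_elem), gb(cout);
  std::copy(GW.begin(), GW.end(), gw.begin());
  gw.attr("dim") = IntegerVector::create(k, k, cin, cout);
  for (int co = 0; co < cout; ++co) gb[co] = (double)GB[co];

  List out = List::create(_["gw"] = gw, _["gb"] = gb);
  if (need_gx) {
    NumericVector gx(GX.n_elem);
    std::copy(GX.begin(), GX.end(), gx.begin());
    gx.attr("dim") = xdim;
    out["gx"] = gx;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector gy, NumericVector y) {
  NumericVector gx(gy.size());
  const double* gp = gy.begin();
  const double* yp = y.begin();
  double* xp = gx.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) xp[i] = yp[i] > 0 ? gp[i] : 0.0;
  gx.attr("dim") = gy.attr("dim");
  return gx;
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector xdim,
                     int k, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int OH = (H + 2 * pad - k) / stride + 1;
  const int OW = (W + 2 * pad - k) / stride + 1;
  NumericVector y((size_t)OH * OW * C * N);
  IntegerVector amax(y.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = amax.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t xoff = (size_t)H * W * (c + (size_t)C * n);
      const size_t yoff = (size_t)OH * OW * (c + (size_t)C * n);
      for (int ow = 0; ow < OW; ++ow)
        for (int oh = 0; oh < OH; ++oh) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int kw = 0; kw < k; ++kw) {
            const int wi = ow * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int hi = oh * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              const double v = xp[xoff + hi + (size_t)H * wi];
              if (v > best) { best = v; besti = (int)(xoff + hi + (size_t)H * wi); }
            }
          }
          yp[yoff + oh + (size_t)OH * ow] = best;
          ap[yoff + oh + (size_t)OH * ow] = besti;
        }
    }
  y.attr("dim") = IntegerVector::create(OH, OW, C, N);
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector argmax,
                              IntegerVector xdim) {
  NumericVector gx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[argmax[i]] += gy[i];
  gx.attr("dim") = xdim;
  return gx;
}
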