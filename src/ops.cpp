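// Low-level tensor kernels for the backbone.
//
// Tensor layout everywhere: column-major R arrays of dim (H, W, C, N),
// i.e. element (h, w, c, n) sits at h + H*(w + W*(c + C*n)), 0-based.
// Dense convolution uses im2col + GEMM (Armadillo dispatches to the
// R BLAS); depth-wise convolution and max pooling are direct loops.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_side(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill the im2col matrix: K = kh*kw*Cin rows (r = ki + kh*(kj + kw*c)),
// M = Ho*Wo*N cols (m = ho + Ho*(wo + Wo*n)). Out-of-range taps are zero.
static void im2col(const double* x, int H, int W, int C, int N,
                   int kh, int kw, int stride, int pad,
                   arma::mat& Xcol) {
  const int Ho = out_side(H, kh, stride, pad);
  const int Wo = out_side(W, kw, stride, pad);
  Xcol.zeros();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int m = ho + Ho * (wo + Wo * n);
        double* col = Xcol.colptr(m);
        for (int c = 0; c < C; ++c) {
          const double* xc = x + (size_t)H * W * (c + (size_t)C * n);
          for (int kj = 0; kj < kw; ++kj) {
            const int wi = wo * stride + kj - pad;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int hi = ho * stride + ki - pad;
              if (hi < 0 || hi >= H) continue;
              col[ki + kh * (kj + kw * c)] = xc[hi + H * wi];
            }
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& Xcol, int H, int W, int C, int N,
                   int kh, int kw, int stride, int pad, double* dx) {
  const int Ho = out_side(H, kh, stride, pad);
  const int Wo = out_side(W, kw, stride, pad);
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int m = ho + Ho * (wo + Wo * n);
        const double* col = Xcol.colptr(m);
        for (int c = 0; c < C; ++c) {
          double* xc = dx + (size_t)H * W * (c + (size_t)C * n);
          for (int kj = 0; kj < kw; ++kj) {
            const int wi = wo * stride + kj - pad;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int hi = ho * stride + ki - pad;
              if (hi < 0 || hi >= H) continue;
              xc[hi + H * wi] += col[ki + kh * (kj + kw * c)];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  const int Ho = out_side(H, kh, stride, pad);
  const int Wo = out_side(W, kw, stride, pad);
  const int K = kh * kw * C, M = Ho * Wo * N;

  arma::mat Wmat(Cout, K);
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < C; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          Wmat(co, ki + kh * (kj + kw * c)) =
            w[ki + kh * (kj + kw * ((size_t)c + (size_t)Cin * co))];

  arma::mat Xcol(K, M);
  im2col(REAL(x), H, W, C, N, kh, kw, stride, pad, Xcol);
  arma::mat Y = Wmat * Xcol;  // Cout x M

  NumericVector out(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * Cout * N));
  double* o = REAL(out);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double bc = b[co];
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          o[ho + Ho * (wo + Wo * ((size_t)co + (size_t)Cout * n))] =
            Y(co, ho + Ho * (wo + Wo * n)) + bc;
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = out_side(H, kh, stride, pad);
  const int Wo = out_side(W, kw, stride, pad);
  const int K = kh * kw * C, M = Ho * Wo * N;

  arma::mat dY(Cout, M);
  const double* g = REAL(dy);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          dY(co, ho + Ho * (wo + Wo * n)) =
            g[ho + Ho * (wo + Wo * ((size_t)co + (size_t)Cout * n))];

  arma::mat Xcol(K, M);
  im2col(REAL(x), H, W, C, N, kh, kw, stride, pad, Xcol);

  arma::mat dWmat = dY * Xcol.t();        // Cout x K
  arma::vec db = arma::sum(dY, 1);        // Cout

  arma::mat Wmat(Cout, K);
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < C; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          Wmat(co, ki + kh * (kj + kw * c)) =
            w[ki + kh * (kj + kw * ((size_t)c + (size_t)C * co))];
  arma::mat dXcol = Wmat.t() * dY;        // K x M

  NumericVector dx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
  std::fill(REAL(dx), REAL(dx) + (R_xlen_t)H * W * C * N, 0.0);
  col2im(dXcol, H, W, C, N, kh, kw, stride, pad, REAL(dx));
  dx.attr("dim") = xd;

  NumericVector dw(Rf_allocVector(REALSXP, (R_xlen_t)kh * kw * C * Cout));
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < C; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          dw[ki + kh * (kj + kw * ((size_t)c + (size_t)C * co))] =
            dWmat(co, ki + kh * (kj + kw * c));
  dw.attr("dim") = wd;

  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Depth-wise convolution: one k x k filter per channel, no channel mixing.
// [[Rcpp::export]]
NumericVector cpp_dwconv_forward(NumericVector x, NumericVector w,
                                 NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  if (wd[2] != C) stop("dwconv: channel mismatch");
  const int Ho = out_side(H, kh, stride, pad);
  const int Wo = out_side(W, kw, stride, pad);

  NumericVector out(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * C * N));
  double* o = REAL(out);
  const double* xp = REAL(x);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
      double* oc = o + (size_t)Ho * Wo * (c + (size_t)C * n);
      const double* wc = REAL(w) + (size_t)kh * kw * c;
      const double bc = b[c];
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = bc;
          for (int kj = 0; kj < kw; ++kj) {
            const int wi = wo * stride + kj - pad;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int hi = ho * stride + ki - pad;
              if (hi < 0 || hi >= H) continue;
              acc += wc[ki + kh * kj] * xc[hi + H * wi];
            }
          }
          oc[ho + Ho * wo] = acc;
        }
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return out;
}

// [[Rcpp::export]]
List cpp_dwconv_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  const int Ho = out_side(H, kh, stride, pad);
  const int Wo = out_side(W, kw, stride, pad);

  NumericVector dx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
  std::fill(REAL(dx), REAL(dx) + (R_xlen_t)H * W * C * N, 0.0);
  NumericVector dw(Rf_allocVector(REALSXP, (R_xlen_t)kh * kw * C));
  std::fill(REAL(dw), REAL(dw) + (R_xlen_t)kh * kw * C, 0.0);
  NumericVector db(C);

  const double* xp = REAL(x);
  const double* gp = REAL(dy);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)H * W * (c + (size_t)C * n);
      const double* gc = gp + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* dxc = REAL(dx) + (size_t)H * W * (c + (size_t)C * n);
      double* dwc = REAL(dw) + (size_t)kh * kw * c;
      const double* wc = REAL(w) + (size_t)kh * kw * c;
      double dbc = 0.0;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = gc[ho + Ho * wo];
          dbc += g;
          for (int kj = 0; kj < kw; ++kj) {
            const int wi = wo * stride + kj - pad;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int hi = ho * stride + ki - pad;
              if (hi < 0 || hi >= H) continue;
              dwc[ki + kh * kj] += g * xc[hi + H * wi];
              dxc[hi + H * wi] += g * wc[ki + kh * kj];
            }
          }
        }
      db[c] += dbc;
    }
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = out_side(H, k, stride, pad);
  const int Wo = out_side(W, k, stride, pad);

  NumericVector out(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * C * N));
  IntegerVector idx(Rf_allocVector(INTSXP, (R_xlen_t)Ho * Wo * C * N));
  const double* xp = REAL(x);
  double* o = REAL(out);
  int* ip = INTEGER(idx);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t xoff = (size_t)H * W * (c + (size_t)C * n);
      const size_t ooff = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          int barg = -1;
          for (int kj = 0; kj < k; ++kj) {
            const int wi = wo * stride + kj - pad;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int hi = ho * stride + ki - pad;
              if (hi < 0 || hi >= H) continue;
              const double v = xp[xoff + hi + H * wi];
              if (v > best) { best = v; barg = hi + H * wi; }
            }
          }
          o[ooff + ho + Ho * wo] = best;
          ip[ooff + ho + Ho * wo] = (int)(xoff + barg) + 1;  // 1-based into x
        }
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = out.attr("dim");
  return List::create(_["y"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(IntegerVector idx, NumericVector dy,
                                   IntegerVector xdim) {
  R_xlen_t nx = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(Rf_allocVector(REALSXP, nx));
  std::fill(REAL(dx), REAL(dx) + nx, 0.0);
  const int* ip = INTEGER(idx);
  const double* g = REAL(dy);
  for (R_xlen_t i = 0; i < dy.size(); ++i) REAL(dx)[ip[i] - 1] += g[i];
  dx.attr("dim") = xdim;
  return dx;
}
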