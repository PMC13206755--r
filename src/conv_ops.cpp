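// Batched 2-D convolution (stride 1, odd kernel, "same" zero padding) via
// im2col + GEMM, with the matching backward pass. Arrays are R arrays in
// [H, W, C, N] layout (column-major); weights are [k, k, Cin, Cout].
// The im2col buffer is laid out (H*W) x (k*k*Cin) so every copy runs down
// contiguous columns.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// M: (H*W) x (k*k*C); column (kh, kw, c) holds the shifted image plane
static void im2col_hw(const double* x, int H, int W, int C, int k, arma::mat& M) {
  const int p = (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  M.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + HW * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        double* col = M.colptr(kh + k * kw + k * k * c);
        for (int w = 0; w < W; ++w) {
          const int ws = w + kw - p;
          if (ws < 0 || ws >= W) continue;
          const int h0 = std::max(0, p - kh), h1 = std::min(H, H + p - kh);
          const double* src = xc + (size_t)H * ws + (h0 + kh - p);
          double* dst = col + (size_t)H * w + h0;
          std::copy(src, src + (h1 - h0), dst);
        }
      }
    }
  }
}

static void col2im_hw(const arma::mat& M, int H, int W, int C, int k, double* gx) {
  const int p = (k - 1) / 2;
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    double* gc = gx + HW * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const double* col = M.colptr(kh + k * kw + k * k * c);
        for (int w = 0; w < W; ++w) {
          const int ws = w + kw - p;
          if (ws < 0 || ws >= W) continue;
          const int h0 = std::max(0, p - kh), h1 = std::min(H, H + p - kh);
          double* dst = gc + (size_t)H * ws + (h0 + kh - p);
          const double* src = col + (size_t)H * w + h0;
          for (int h = 0; h < h1 - h0; ++h) dst[h] += src[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(NumericVector x, IntegerVector xdim,
                            NumericVector w, IntegerVector wdim,
                            NumericVector b) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int k = wdim[0], Cin = wdim[2], Cout = wdim[3];
  if (Cin != C) stop("conv2d: input has %d channels but weights expect %d", C, Cin);
  const size_t HW = (size_t)H * W;
  NumericVector out(HW * Cout * N);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  arma::mat M;
  if (k > 1) M.set_size(HW, (size_t)k * k * Cin);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + HW * C * n;
    arma::mat O(out.begin() + HW * Cout * n, HW, Cout, false, true);
    if (k == 1) {
      arma::mat X(const_cast<double*>(xn), HW, C, false, true);
      O = X * Wm;
    } else {
      im2col_hw(xn, H, W, C, k, M);
      O = M * Wm;
    }
    O.each_row() += bv;
  }
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return out;
}

// [[Rcpp::export]]
List conv2d_bw_cpp(NumericVector x, IntegerVector xdim,
                   NumericVector w, IntegerVector wdim,
                   NumericVector gout) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int k = wdim[0], Cin = wdim[2], Cout = wdim[3];
  const size_t HW = (size_t)H * W;
  NumericVector gx(x.size()), gw(w.size()), gb(Cout);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout, false, true);
  arma::mat GW(gw.begin(), (size_t)k * k * Cin, Cout, false, true);
  arma::rowvec GB(gb.begin(), Cout, false, true);
  arma::mat M, GM;
  if (k > 1) {
    M.set_size(HW, (size_t)k * k * Cin);
    GM.set_size(HW, (size_t)k * k * Cin);
  }
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + HW * C * n;
    arma::mat G(const_cast<double*>(gout.begin()) + HW * Cout * n, HW, Cout, false, true);
    GB += arma::sum(G, 0);
    if (k == 1) {
      arma::mat X(const_cast<double*>(xn), HW, C, false, true);
      GW += X.t() * G;
      arma::mat GX(gx.begin() + HW * C * n, HW, C, false, true);
      GX = G * Wm.t();
    } else {
      im2col_hw(xn, H, W, C, k, M);
      GW += M.t() * G;
      GM = G * Wm.t();
      col2im_hw(GM, H, W, C, k, gx.begin() + HW * C * n);
    }
  }
  gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
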