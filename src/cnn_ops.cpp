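// Convolution and pooling kernels for the compact event classifier.
// Batches are column-major R arrays with dims (H, W, C, N); convolution is
// 3x3 (k odd), stride 1, same padding, realized as im2col + one matrix
// product per sample so the heavy lifting stays in BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col: patches matrix (k*k*Cin x H*W); row index = (c*k + dw)*k + dh
static void im2col(const double* x, int H, int W, int C, int k, arma::mat& P) {
  const int half = k / 2;
  P.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int dw = -half; dw <= half; ++dw) {
      for (int dh = -half; dh <= half; ++dh) {
        const int row = (c * k + (dw + half)) * k + (dh + half);
        for (int w = 0; w < W; ++w) {
          const int ws = w + dw;
          if (ws < 0 || ws >= W) continue;
          const double* src = xc + (size_t)ws * H;
          double* dst = P.memptr() + (size_t)row + (size_t)w * H * P.n_rows;
          for (int h = 0; h < H; ++h) {
            const int hs = h + dh;
            if (hs < 0 || hs >= H) continue;
            dst[(size_t)h * P.n_rows] = src[hs];
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2col
static void col2im(const arma::mat& P, int H, int W, int C, int k, double* dx) {
  const int half = k / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int dw = -half; dw <= half; ++dw) {
      for (int dh = -half; dh <= half; ++dh) {
        const int row = (c * k + (dw + half)) * k + (dh + half);
        for (int w = 0; w < W; ++w) {
          const int ws = w + dw;
          if (ws < 0 || ws >= W) continue;
          double* dst = xc + (size_t)ws * H;
          const double* src = P.memptr() + (size_t)row + (size_t)w * H * P.n_rows;
          for (int h = 0; h < H; ++h) {
            const int hs = h + dh;
            if (hs < 0 || hs >= H) continue;
            dst[hs] += src[(size_t)h * P.n_rows];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, IntegerVector dims, arma::mat Wt,
                        arma::vec b, int k) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Cout = Wt.n_rows;
  NumericVector y((size_t)H * W * Cout * N);
  arma::mat P(k * k * C, H * W);
  for (int n = 0; n < N; ++n) {
    im2col(REAL(x) + (size_t)n * H * W * C, H, W, C, k, P);
    arma::mat Y = Wt * P;                  // Cout x HW
    Y.each_col() += b;
    double* yp = REAL(y) + (size_t)n * H * W * Cout;
    for (int c = 0; c < Cout; ++c)
      for (int s = 0; s < H * W; ++s)
        yp[(size_t)c * H * W + s] = Y(c, s);
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, IntegerVector dims, arma::mat Wt, int k,
               NumericVector dy) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Cout = Wt.n_rows;
  arma::mat dW(Cout, k * k * C, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericVector dx((size_t)H * W * C * N);
  arma::mat P(k * k * C, H * W);
  arma::mat dY(Cout, H * W);
  for (int n = 0; n < N; ++n) {
    im2col(REAL(x) + (size_t)n * H * W * C, H, W, C, k, P);
    const double* dyp = REAL(dy) + (size_t)n * H * W * Cout;
    for (int c = 0; c < Cout; ++c)
      for (int s = 0; s < H * W; ++s)
        dY(c, s) = dyp[(size_t)c * H * W + s];
    dW += dY * P.t();
    db += arma::sum(dY, 1);
    arma::mat dP = Wt.t() * dY;            // kkC x HW
    col2im(dP, H, W, C, k, REAL(dx) + (size_t)n * H * W * C);
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

// 2x2 max pooling, stride 2; returns pooled values and 1-based argmax
// indices into the input array for the backward scatter
// [[Rcpp::export]]
List maxpool2_fw(NumericVector x, IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)(n * C + c) * H * W;
      const size_t obase = (size_t)(n * C + c) * Ho * Wo;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          double best = -1e300; size_t bidx = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              const size_t i = base + (size_t)(2 * w + dw) * H + (2 * h + dh);
              if (REAL(x)[i] > best) { best = REAL(x)[i]; bidx = i; }
            }
          y[obase + (size_t)w * Ho + h] = best;
          idx[obase + (size_t)w * Ho + h] = (int)(bidx + 1);
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw(NumericVector dy, IntegerVector idx,
                          IntegerVector in_dims) {
  NumericVector dx((size_t)in_dims[0] * in_dims[1] * in_dims[2] * in_dims[3]);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  dx.attr("dim") = in_dims;
  return dx;
}
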