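// Dilated 2D convolution forward/backward via im2col + GEMM.
//
// Tensor layout everywhere: column-major (C, H, W, N), i.e. element
// (c, i, j, n) sits at c + C*(i + H*(j + W*n)). Weights for a k x k conv
// are (Cout, Cin*k*k) with column index (kr*k + kc)*Cin + c, which keeps
// the channel dimension contiguous so im2col reduces to block copies.
// Padding is dilation*(k-1)/2, so spatial dimensions are preserved.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int C, int H, int W, int k, int dil,
                   arma::mat& col) {
  const int pad = dil * (k - 1) / 2;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double* dst = col.colptr(i + (std::size_t)H * j);
      for (int kr = 0; kr < k; ++kr) {
        const int ii = i + kr * dil - pad;
        const bool rowOk = (ii >= 0 && ii < H);
        for (int kc = 0; kc < k; ++kc) {
          const int jj = j + kc * dil - pad;
          double* d = dst + (std::size_t)(kr * k + kc) * C;
          if (rowOk && jj >= 0 && jj < W) {
            const double* s = x + (std::size_t)C * (ii + (std::size_t)H * jj);
            std::copy(s, s + C, d);
          } else {
            std::fill(d, d + C, 0.0);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, IntegerVector dims,
                                 const arma::mat& wgt, const arma::vec& bias,
                                 int k, int dil) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int Cout = wgt.n_rows;
  if ((int)wgt.n_cols != C * k * k)
    stop("weight shape does not match input channels / kernel");
  NumericVector y((std::size_t)Cout * H * W * N);
  arma::mat col(C * k * k, (std::size_t)H * W);
  const std::size_t xs = (std::size_t)C * H * W;
  const std::size_t ys = (std::size_t)Cout * H * W;
  for (int n = 0; n < N; ++n) {
    im2col(&x[xs * n], C, H, W, k, dil, col);
    arma::mat yn = wgt * col;  // Cout x (H*W)
    yn.each_col() += bias;
    std::copy(yn.memptr(), yn.memptr() + ys, y.begin() + ys * n);
  }
  y.attr("dim") = IntegerVector::create(Cout, H, W, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, IntegerVector dims,
                         const arma::mat& wgt, NumericVector dy,
                         int k, int dil) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int Cout = wgt.n_rows;
  const int pad = dil * (k - 1) / 2;
  arma::mat dW(Cout, C * k * k, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericVector dx(x.size());
  arma::mat col(C * k * k, (std::size_t)H * W);
  const std::size_t xs = (std::size_t)C * H * W;
  const std::size_t ys = (std::size_t)Cout * H * W;
  for (int n = 0; n < N; ++n) {
    im2col(&x[xs * n], C, H, W, k, dil, col);
    const arma::mat dyn(const_cast<double*>(&dy[ys * n]), Cout,
                        (std::size_t)H * W, false, true);
    dW += dyn * col.t();
    db += arma::sum(dyn, 1);
    arma::mat dcol = wgt.t() * dyn;  // (C*k*k) x (H*W)
    double* dxn = &dx[xs * n];
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const double* src = dcol.colptr(i + (std::size_t)H * j);
        for (int kr = 0; kr < k; ++kr) {
          const int ii = i + kr * dil - pad;
          if (ii < 0 || ii >= H) continue;
          for (int kc = 0; kc < k; ++kc) {
            const int jj = j + kc * dil - pad;
            if (jj < 0 || jj >= W) continue;
            const double* s = src + (std::size_t)(kr * k + kc) * C;
            double* d = dxn + (std::size_t)C * (ii + (std::size_t)H * jj);
            for (int c = 0; c < C; ++c) d[c] += s[c];
          }
        }
      }
    }
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dw"] = dW, _["db"] = db);
}

// Batch normalization over a (C, M) matrix (channels x flattened pixels),
// exploiting that each column (all channels of one pixel) is contiguous.

// [[Rcpp::export]]
List cpp_bn_forward(const arma::mat& x, const arma::vec& gamma,
                    const arma::vec& beta, double eps) {
  const int C = x.n_rows;
  const std::size_t M = x.n_cols;
  arma::vec sum(C, arma::fill::zeros), sumsq(C, arma::fill::zeros);
  for (std::size_t m = 0; m < M; ++m) {
    const double* p = x.colptr(m);
    for (int c = 0; c < C; ++c) { sum[c] += p[c]; sumsq[c] += p[c] * p[c]; }
  }
  arma::vec mean = sum / (double)M;
  arma::vec var = sumsq / (double)M - mean % mean;
  var.transform([](double v) { return v < 0 ? 0.0 : v; });
  arma::vec istd = 1.0 / arma::sqrt(var + eps);
  arma::mat y(C, M);
  for (std::size_t m = 0; m < M; ++m) {
    const double* p = x.colptr(m);
    double* q = y.colptr(m);
    for (int c = 0; c < C; ++c)
      q[c] = gamma[c] * (p[c] - mean[c]) * istd[c] + beta[c];
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var,
                      _["istd"] = istd);
}

// [[Rcpp::export]]
arma::mat cpp_bn_affine(const arma::mat& x, const arma::vec& gamma,
                        const arma::vec& beta, const arma::vec& mean,
                        const arma::vec& istd) {
  const int C = x.n_rows;
  const std::size_t M = x.n_cols;
  arma::mat y(C, M);
  for (std::size_t m = 0; m < M; ++m) {
    const double* p = x.colptr(m);
    double* q = y.colptr(m);
    for (int c = 0; c < C; ++c)
      q[c] = gamma[c] * (p[c] - mean[c]) * istd[c] + beta[c];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_bn_backward(const arma::mat& x, const arma::vec& mean,
                     const arma::vec& istd, const arma::vec& gamma,
                     const arma::mat& dy) {
  const int C = x.n_rows;
  const std::size_t M = x.n_cols;
  arma::vec sdy(C, arma::fill::zeros), sdyx(C, arma::fill::zeros);
  for (std::size_t m = 0; m < M; ++m) {
    const double* p = x.colptr(m);
    const double* g = dy.colptr(m);
    for (int c = 0; c < C; ++c) {
      const double xh = (p[c] - mean[c]) * istd[c];
      sdy[c] += g[c];
      sdyx[c] += g[c] * xh;
    }
  }
  arma::mat dx(C, M);
  const double invM = 1.0 / (double)M;
  for (std::size_t m = 0; m < M; ++m) {
    const double* p = x.colptr(m);
    const double* g = dy.colptr(m);
    double* q = dx.colptr(m);
    for (int c = 0; c < C; ++c) {
      const double xh = (p[c] - mean[c]) * istd[c];
      q[c] = gamma[c] * istd[c] * (g[c] - invM * (sdy[c] + xh * sdyx[c]));
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = sdyx, _["dbeta"] = sdy);
}
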