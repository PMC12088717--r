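// Minimal convolutional primitives for the audit networks.
// Layout conventions: a feature map is an (H, W, C) cube (column-major, as an
// R array); conv weights are a (k*k*Cin) x Cout matrix whose row index is
// c*k*k + di*k + dj; an im2col row index is i + Ho*j (column-major over the
// output grid), so reshape(Y.col(co), Ho, Wo) recovers the R array layout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col(const cube& x, int k, int stride, int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(Ho * Wo, k * k * C);
  for (int c = 0; c < C; ++c) {
    for (int di = 0; di < k; ++di) {
      for (int dj = 0; dj < k; ++dj) {
        const int col = c * k * k + di * k + dj;
        for (int j = 0; j < Wo; ++j) {
          const int jj = j * stride + dj - pad;
          for (int i = 0; i < Ho; ++i) {
            const int ii = i * stride + di - pad;
            out(i + Ho * j, col) =
              (ii >= 0 && ii < H && jj >= 0 && jj < W) ? x(ii, jj, c) : 0.0;
          }
        }
      }
    }
  }
  return out;
}

static cube col2im(const mat& dxc, int H, int W, int C, int k, int stride,
                   int pad, int Ho, int Wo) {
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int di = 0; di < k; ++di) {
      for (int dj = 0; dj < k; ++dj) {
        const int col = c * k * k + di * k + dj;
        for (int j = 0; j < Wo; ++j) {
          const int jj = j * stride + dj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int ii = i * stride + di - pad;
            if (ii < 0 || ii >= H) continue;
            dx(ii, jj, c) += dxc(i + Ho * j, col);
          }
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, int k, int stride, int pad) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (Wd + 2 * pad - k) / stride + 1;
  const int Cout = W.n_cols;
  mat xc = im2col(x, k, stride, pad, Ho, Wo);
  mat y = xc * W;
  y.each_row() += b.t();
  cube out(Ho, Wo, Cout);
  for (int co = 0; co < Cout; ++co)
    out.slice(co) = reshape(y.col(co), Ho, Wo);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& W,
                          const arma::cube& gy, int k, int stride, int pad) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int Ho = gy.n_rows, Wo = gy.n_cols, Cout = gy.n_slices;
  mat g(Ho * Wo, Cout);
  for (int co = 0; co < Cout; ++co)
    g.col(co) = vectorise(gy.slice(co));
  mat xc = im2col(x, k, stride, pad, Ho, Wo);
  mat dW = xc.t() * g;
  vec db = sum(g, 0).t();
  mat dxc = g * W.t();
  cube dx = col2im(dxc, H, Wd, C, k, stride, pad, Ho, Wo);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// 2x2 max pooling, stride 2; idx stores the winning offset 0..3 (di + 2*dj)
// [[Rcpp::export]]
Rcpp::List cpp_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C), idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = x(2 * i, 2 * j, c);
        int bid = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; bid = di + 2 * dj; }
          }
        y(i, j, c) = best;
        idx(i, j, c) = bid;
      }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube& gy, const arma::cube& idx) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  cube dx(2 * Ho, 2 * Wo, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const int bid = (int)idx(i, j, c);
        dx(2 * i + bid % 2, 2 * j + bid / 2, c) = gy(i, j, c);
      }
  return dx;
}

// [[Rcpp::export]]
arma::cube cpp_avgpool2_fwd(const arma::cube& x) {
  const int Ho = x.n_rows / 2, Wo = x.n_cols / 2, C = x.n_slices;
  cube y(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        y(i, j, c) = 0.25 * (x(2 * i, 2 * j, c) + x(2 * i + 1, 2 * j, c) +
                             x(2 * i, 2 * j + 1, c) + x(2 * i + 1, 2 * j + 1, c));
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_avgpool2_bwd(const arma::cube& gy) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  cube dx(2 * Ho, 2 * Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const double g = 0.25 * gy(i, j, c);
        dx(2 * i, 2 * j, c) = g;
        dx(2 * i + 1, 2 * j, c) = g;
        dx(2 * i, 2 * j + 1, c) = g;
        dx(2 * i + 1, 2 * j + 1, c) = g;
      }
  return dx;
}

// nearest-neighbour 2x upsampling
// [[Rcpp::export]]
arma::cube cpp_upsample2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(const arma::cube& gy) {
  const int Ho = gy.n_rows / 2, Wo = gy.n_cols / 2, C = gy.n_slices;
  cube dx(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        dx(i, j, c) = gy(2 * i, 2 * j, c) + gy(2 * i + 1, 2 * j, c) +
                      gy(2 * i, 2 * j + 1, c) + gy(2 * i + 1, 2 * j + 1, c);
  return dx;
}
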