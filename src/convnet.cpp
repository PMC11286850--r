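// Convolution / pooling kernels backing the contact-map predictor.
// Tensors are column-major: 1D activations are L x C matrices (length x
// channels), 2D activations are H x W x C cubes. Convolution weights are
// stored tap-major as (k * Cin) x Cout matrices: rows [t*Cin, (t+1)*Cin)
// hold tap t. All convolutions use "same" zero padding and odd kernels.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
arma::mat cnn_conv1d_fwd(const arma::mat& X, const arma::mat& W,
                         const arma::vec& b, int k, int dilation) {
  const int L = X.n_rows, Cin = X.n_cols;
  const int pad = (k - 1) / 2 * dilation;
  mat Y(L, W.n_cols, fill::zeros);
  Y.each_row() += b.t();
  for (int t = 0; t < k; ++t) {
    const int s = t * dilation - pad;  // y[i] += x[i + s] * W_t
    const int i0 = std::max(0, -s), i1 = std::min(L - 1, L - 1 - s);
    if (i0 > i1) continue;
    Y.rows(i0, i1) += X.rows(i0 + s, i1 + s) * W.rows(t * Cin, t * Cin + Cin - 1);
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cnn_conv1d_bwd(const arma::mat& X, const arma::mat& W,
                          const arma::mat& Gy, int k, int dilation,
                          bool need_gx) {
  const int L = X.n_rows, Cin = X.n_cols;
  const int pad = (k - 1) / 2 * dilation;
  mat Gx;
  if (need_gx) Gx.zeros(L, Cin);
  mat Gw(W.n_rows, W.n_cols, fill::zeros);
  for (int t = 0; t < k; ++t) {
    const int s = t * dilation - pad;
    const int i0 = std::max(0, -s), i1 = std::min(L - 1, L - 1 - s);
    if (i0 > i1) continue;
    const mat Wt = W.rows(t * Cin, t * Cin + Cin - 1);
    if (need_gx) Gx.rows(i0 + s, i1 + s) += Gy.rows(i0, i1) * Wt.t();
    Gw.rows(t * Cin, t * Cin + Cin - 1) = X.rows(i0 + s, i1 + s).t() * Gy.rows(i0, i1);
  }
  vec Gb = sum(Gy, 0).t();
  return Rcpp::List::create(Rcpp::Named("gx") = Gx,
                            Rcpp::Named("gw") = Gw,
                            Rcpp::Named("gb") = Gb);
}

// [[Rcpp::export]]
Rcpp::List cnn_maxpool2_fwd(const arma::mat& X) {
  const int L = X.n_rows, C = X.n_cols, Lo = L / 2;
  mat Y(Lo, C);
  umat idx(Lo, C);  // 0 or 1: which of the pair won
  for (int c = 0; c < C; ++c) {
    for (int i = 0; i < Lo; ++i) {
      const double a = X(2 * i, c), b = X(2 * i + 1, c);
      if (a >= b) { Y(i, c) = a; idx(i, c) = 0; }
      else        { Y(i, c) = b; idx(i, c) = 1; }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::mat cnn_maxpool2_bwd(const arma::mat& Gy, const arma::umat& idx, int L) {
  const int Lo = Gy.n_rows, C = Gy.n_cols;
  mat Gx(L, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int i = 0; i < Lo; ++i)
      Gx(2 * i + idx(i, c), c) = Gy(i, c);
  return Gx;
}

// 2D convolution over H x W x Cin cube; weights ((k*k*Cin) x Cout),
// tap-major with row index (ti*k + tj)*Cin + ci.
// [[Rcpp::export]]
arma::cube cnn_conv2d_fwd(const arma::cube& X, const arma::mat& W,
                          const arma::vec& b, int k, int dilation) {
  const int H = X.n_rows, Wd = X.n_cols, Cin = X.n_slices;
  const int Cout = W.n_cols;
  const int pad = (k - 1) / 2 * dilation;
  cube Y(H, Wd, Cout);
  for (int co = 0; co < Cout; ++co) Y.slice(co).fill(b(co));
  for (int ti = 0; ti < k; ++ti) {
    const int si = ti * dilation - pad;
    const int r0 = std::max(0, -si), r1 = std::min(H - 1, H - 1 - si);
    if (r0 > r1) continue;
    for (int tj = 0; tj < k; ++tj) {
      const int sj = tj * dilation - pad;
      const int c0 = std::max(0, -sj), c1 = std::min(Wd - 1, Wd - 1 - sj);
      if (c0 > c1) continue;
      for (int ci = 0; ci < Cin; ++ci) {
        const mat Xs = X.slice(ci).submat(r0 + si, c0 + sj, r1 + si, c1 + sj);
        const int wrow = (ti * k + tj) * Cin + ci;
        for (int co = 0; co < Cout; ++co) {
          const double w = W(wrow, co);
          if (w != 0.0) Y.slice(co).submat(r0, c0, r1, c1) += w * Xs;
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cnn_conv2d_bwd(const arma::cube& X, const arma::mat& W,
                          const arma::cube& Gy, int k, int dilation,
                          bool need_gx) {
  const int H = X.n_rows, Wd = X.n_cols, Cin = X.n_slices;
  const int Cout = W.n_cols;
  const int pad = (k - 1) / 2 * dilation;
  cube Gx;
  if (need_gx) Gx.zeros(H, Wd, Cin);
  mat Gw(W.n_rows, W.n_cols, fill::zeros);
  vec Gb(Cout, fill::zeros);
  for (int co = 0; co < Cout; ++co) Gb(co) = accu(Gy.slice(co));
  for (int ti = 0; ti < k; ++ti) {
    const int si = ti * dilation - pad;
    const int r0 = std::max(0, -si), r1 = std::min(H - 1, H - 1 - si);
    if (r0 > r1) continue;
    for (int tj = 0; tj < k; ++tj) {
      const int sj = tj * dilation - pad;
      const int c0 = std::max(0, -sj), c1 = std::min(Wd - 1, Wd - 1 - sj);
      if (c0 > c1) continue;
      for (int ci = 0; ci < Cin; ++ci) {
        const mat Xs = X.slice(ci).submat(r0 + si, c0 + sj, r1 + si, c1 + sj);
        const int wrow = (ti * k + tj) * Cin + ci;
        for (int co = 0; co < Cout; ++co) {
          const mat Gys = Gy.slice(co).submat(r0, c0, r1, c1);
          Gw(wrow, co) += accu(Xs % Gys);
          if (need_gx)
            Gx.slice(ci).submat(r0 + si, c0 + sj, r1 + si, c1 + sj) += W(wrow, co) * Gys;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = Gx,
                            Rcpp::Named("gw") = Gw,
                            Rcpp::Named("gb") = Gb);
}

// Fused per-sample channel normalization + ReLU (1D activations L x C).
// [[Rcpp::export]]
Rcpp::List cnn_norm_relu_fwd(const arma::mat& X, const arma::vec& gamma,
                             const arma::vec& beta, double eps) {
  const int L = X.n_rows, C = X.n_cols;
  mat Xhat(L, C), Y(L, C);
  vec isd(C);
  for (int c = 0; c < C; ++c) {
    const double mu = mean(X.col(c));
    const double v = mean(square(X.col(c) - mu));
    isd(c) = 1.0 / std::sqrt(v + eps);
    Xhat.col(c) = (X.col(c) - mu) * isd(c);
    Y.col(c) = clamp(gamma(c) * Xhat.col(c) + beta(c), 0.0, datum::inf);
  }
  return Rcpp::List::create(Rcpp::Named("y") = Y,
                            Rcpp::Named("xhat") = Xhat,
                            Rcpp::Named("isd") = isd);
}

// [[Rcpp::export]]
Rcpp::List cnn_norm_relu_bwd(const arma::mat& Gy, const arma::mat& Y,
                             const arma::mat& Xhat, const arma::vec& isd,
                             const arma::vec& gamma) {
  const int L = Gy.n_rows, C = Gy.n_cols;
  mat Gx(L, C);
  vec gg(C), gb(C);
  for (int c = 0; c < C; ++c) {
    vec g = Gy.col(c) % conv_to<vec>::from(Y.col(c) > 0);
    gg(c) = dot(g, Xhat.col(c));
    gb(c) = accu(g);
    vec gxhat = g * gamma(c);
    const double m1 = mean(gxhat);
    const double m2 = mean(gxhat % Xhat.col(c));
    Gx.col(c) = isd(c) * (gxhat - m1 - Xhat.col(c) * m2);
  }
  return Rcpp::List::create(Rcpp::Named("gx") = Gx,
                            Rcpp::Named("ggamma") = gg,
                            Rcpp::Named("gbeta") = gb);
}
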