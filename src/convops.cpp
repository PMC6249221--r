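// 1-D convolution and max-pooling primitives for the CNN engine.
// Layout: signals are cubes (channels x length x batch); conv weights are
// (out_channels x in_channels*kernel) so the forward pass is one GEMM per
// batch element over an im2col matrix (in_channels*kernel x out_length).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void im2col1d(const mat& x, int kernel, int pad, mat& cols) {
  // x: (C x L). cols: (C*kernel x Lout), Lout = L + 2*pad - kernel + 1.
  const int C = x.n_rows, L = x.n_cols;
  const int Lout = L + 2 * pad - kernel + 1;
  cols.zeros(C * kernel, Lout);
  for (int kk = 0; kk < kernel; ++kk) {
    // input position feeding output j at tap kk is j + kk - pad
    int j0 = std::max(0, pad - kk);
    int j1 = std::min(Lout, L + pad - kk);
    if (j1 <= j0) continue;
    cols.submat(kk * C, j0, (kk + 1) * C - 1, j1 - 1) =
        x.cols(j0 + kk - pad, j1 - 1 + kk - pad);
  }
}

// [[Rcpp::export(name = ".conv1d_fw")]]
arma::cube conv1d_fw(const arma::cube& X, const arma::mat& W,
                     const arma::vec& b, int kernel, int pad) {
  const int B = X.n_slices;
  const int Lout = (int)X.n_cols + 2 * pad - kernel + 1;
  const int Cout = W.n_rows;
  cube Y(Cout, Lout, B);
  mat cols;
  for (int s = 0; s < B; ++s) {
    im2col1d(X.slice(s), kernel, pad, cols);
    Y.slice(s) = W * cols;
    Y.slice(s).each_col() += b;
  }
  return Y;
}

// [[Rcpp::export(name = ".conv1d_bw")]]
Rcpp::List conv1d_bw(const arma::cube& X, const arma::mat& W,
                     const arma::cube& dY, int kernel, int pad) {
  const int B = X.n_slices;
  const int C = X.n_rows, L = X.n_cols;
  const int Lout = dY.n_cols;
  cube dX(C, L, B, fill::zeros);
  mat dW(W.n_rows, W.n_cols, fill::zeros);
  vec db(W.n_rows, fill::zeros);
  mat cols, dcols;
  for (int s = 0; s < B; ++s) {
    im2col1d(X.slice(s), kernel, pad, cols);
    dW += dY.slice(s) * cols.t();
    db += sum(dY.slice(s), 1);
    dcols = W.t() * dY.slice(s);  // (C*kernel x Lout)
    // col2im: scatter-add taps back onto the padded time axis
    mat& dx = dX.slice(s);
    for (int kk = 0; kk < kernel; ++kk) {
      int j0 = std::max(0, pad - kk);
      int j1 = std::min(Lout, L + pad - kk);
      if (j1 <= j0) continue;
      dx.cols(j0 + kk - pad, j1 - 1 + kk - pad) +=
          dcols.submat(kk * C, j0, (kk + 1) * C - 1, j1 - 1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export(name = ".maxpool1d_fw")]]
Rcpp::List maxpool1d_fw(const arma::cube& X, int kernel, int stride) {
  const int B = X.n_slices, C = X.n_rows, L = X.n_cols;
  const int Lout = (L - kernel) / stride + 1;
  cube Y(C, Lout, B);
  // argmax stored as 1-based input column index, needed by the backward pass
  cube idx(C, Lout, B);
  for (int s = 0; s < B; ++s) {
    const mat& x = X.slice(s);
    for (int j = 0; j < Lout; ++j) {
      int start = j * stride;
      for (int c = 0; c < C; ++c) {
        double best = x(c, start);
        int besti = start;
        for (int t = start + 1; t < start + kernel; ++t) {
          if (x(c, t) > best) { best = x(c, t); besti = t; }
        }
        Y(c, j, s) = best;
        idx(c, j, s) = besti + 1;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool1d_bw")]]
arma::cube maxpool1d_bw(const arma::cube& dY, const arma::cube& idx, int Lin) {
  const int B = dY.n_slices, C = dY.n_rows, Lout = dY.n_cols;
  cube dX(C, Lin, B, fill::zeros);
  for (int s = 0; s < B; ++s) {
    for (int j = 0; j < Lout; ++j) {
      for (int c = 0; c < C; ++c) {
        dX(c, (int)idx(c, j, s) - 1, s) += dY(c, j, s);
      }
    }
  }
  return dX;
}
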