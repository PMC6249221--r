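// Core ADMM loop of variational mode decomposition with pinned center
// frequencies. Works on the one-sided (analytic) spectrum of the
// mirror-extended signal, exactly as classical frequency-domain VMD, except
// that modes flagged in `fixed` never have their center frequency updated.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// f: real mirror-extended signal (length T, even)
// omega0: initial center frequencies in cycles/sample; fixed: 1 = pinned
// Returns modes (K x T, real), final omegas, iteration count, convergence flag
// and the per-iteration omega trajectory.
// [[Rcpp::export(name = ".mvmd_core")]]
Rcpp::List mvmd_core(const arma::vec& f, const arma::vec& omega0,
                     const arma::uvec& fixed, double alpha, double tau,
                     double tol, int max_iter) {
  const int T = f.n_elem;
  const int K = omega0.n_elem;
  const int half = T / 2;  // index of the zero-frequency bin after centering

  vec freqs = regspace<vec>(0, T - 1) / T - 0.5;

  cx_vec f_hat = fft(conv_to<cx_vec>::from(f));
  // center the spectrum and keep the positive half (analytic signal)
  cx_vec f_hat_c = shift(f_hat, half);
  cx_vec f_plus(T, fill::zeros);
  f_plus.subvec(half, T - 1) = f_hat_c.subvec(half, T - 1);

  cx_mat u(T, K, fill::zeros);
  cx_vec lambda(T, fill::zeros);
  cx_vec sum_u(T, fill::zeros);
  vec omega = omega0;

  std::vector<vec> omega_hist;
  double udiff = tol + 1.0;
  int n = 0;
  const double eps = std::numeric_limits<double>::epsilon();

  double f_energy = accu(square(abs(f_plus)));
  if (f_energy < eps) {
    // zero-energy input: all-zero modes, centers untouched
    mat modes(K, T, fill::zeros);
    return Rcpp::List::create(
        Rcpp::Named("modes") = modes, Rcpp::Named("omega") = omega,
        Rcpp::Named("n_iters") = 0, Rcpp::Named("converged") = true,
        Rcpp::Named("omega_history") = mat(1, K, fill::zeros));
  }

  while (udiff > tol && n < max_iter) {
    udiff = 0.0;
    for (int k = 0; k < K; ++k) {
      cx_vec u_old = u.col(k);
      sum_u -= u_old;
      cx_vec num = f_plus - sum_u - lambda / 2.0;
      vec denom = 1.0 + alpha * square(freqs - omega(k));
      u.col(k) = num / conv_to<cx_vec>::from(denom);
      sum_u += u.col(k);

      if (!fixed(k)) {
        vec pw = square(abs(u.col(k).subvec(half, T - 1)));
        double e = accu(pw);
        if (e > eps) {
          omega(k) = dot(freqs.subvec(half, T - 1), pw) / e;
        }
      }
      // change relative to total signal energy: robust to near-empty modes
      udiff += accu(square(abs(u.col(k) - u_old))) / f_energy;
    }
    lambda += tau * (sum_u - f_plus);
    omega_hist.push_back(omega);
    ++n;
  }

  // rebuild two-sided spectra by Hermitian symmetry and invert
  mat modes(K, T);
  for (int k = 0; k < K; ++k) {
    cx_vec full(T, fill::zeros);
    full.subvec(half, T - 1) = u.col(k).subvec(half, T - 1);
    for (int i = 1; i < half; ++i) full(i) = std::conj(full(T - i));
    full(0) = std::conj(full(0));
    cx_vec ut = ifft(shift(full, -half));
    modes.row(k) = real(ut).t();
  }

  mat oh(n, K);
  for (int i = 0; i < n; ++i) oh.row(i) = omega_hist[i].t();

  return Rcpp::List::create(
      Rcpp::Named("modes") = modes, Rcpp::Named("omega") = omega,
      Rcpp::Named("n_iters") = n, Rcpp::Named("converged") = (udiff <= tol),
      Rcpp::Named("omega_history") = oh);
}
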