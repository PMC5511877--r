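// Bilinear neural-state integrator for the DCM engine.
//
// dz/dt = (A + sum_j u_j B_j) z + C u, integrated with classical RK4 on a
// fine grid on which the inputs are piecewise constant (boxcars aligned to
// the grid), so u is held fixed within each step.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".dcmIntegrate")]]
arma::mat dcm_integrate(const arma::mat& A, const arma::cube& B,
                        const arma::mat& C, const arma::mat& U,
                        const arma::vec& z0, double dt) {
  const uword T = U.n_rows;
  const uword R = A.n_rows;
  const uword J = U.n_cols;
  mat Z(T, R);
  vec z = z0;
  Z.row(0) = z.t();

  for (uword t = 0; t + 1 < T; ++t) {
    // effective coupling under the inputs active during this step
    mat M = A;
    for (uword j = 0; j < J; ++j) {
      double uj = U(t, j);
      if (uj != 0.0) M += uj * B.slice(j);
    }
    vec drive = C * U.row(t).t();

    vec k1 = M * z + drive;
    vec k2 = M * (z + 0.5 * dt * k1) + drive;
    vec k3 = M * (z + 0.5 * dt * k2) + drive;
    vec k4 = M * (z + dt * k3) + drive;
    z += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    Z.row(t + 1) = z.t();
  }
  return Z;
}

// [[Rcpp::export(name = ".dcmConvolve")]]
arma::mat dcm_convolve(const arma::mat& Z, const arma::vec& kernel) {
  // causal convolution, truncated to the input length
  mat out(Z.n_rows, Z.n_cols);
  for (uword r = 0; r < Z.n_cols; ++r) {
    vec full = conv(Z.col(r), kernel);
    out.col(r) = full.head(Z.n_rows);
  }
  return out;
}
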