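// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Deflationary FastICA with the logcosh (tanh) contrast on pre-whitened data.
//
// Z      : r x p whitened data (rows ~ unit variance except numerically
//          degenerate directions, which carry near-zero variance)
// W0     : r x n_comp matrix of initial unit vectors (columns), typically an
//          orthogonalized Gaussian matrix drawn in R so that all randomness
//          is seeded on the R side
// tol    : convergence tolerance on |<w_new, w_old>| (1 - tol)
// max_iter: iteration cap per component; a component hitting the cap is kept
//          (Gaussian-subspace directions have no stable fixed point and will
//          wander to the cap; they are genuine directions, not failures)
// exhaust_tol: deflation stops when no direction orthogonal to the already
//          extracted ones carries variance above this threshold ("variance
//          exhaustion" under overextraction of rank-deficient mixtures)
//
// Returns W (r x k extracted), converged flags, iteration counts.
// [[Rcpp::export(name = ".fastica_deflate_cpp")]]
Rcpp::List fastica_deflate(const arma::mat& Z, const arma::mat& W0,
                           double tol, int max_iter, double exhaust_tol) {
  const uword r = Z.n_rows;
  const double p = static_cast<double>(Z.n_cols);
  const uword n_comp = W0.n_cols;

  mat Cz = (Z * Z.t()) / (p - 1.0);   // r x r, cheap: r is small
  mat W(r, n_comp, fill::zeros);
  std::vector<int> conv, iters;
  uword k = 0;

  for (uword c = 0; c < n_comp; ++c) {
    // variance exhaustion: largest eigenvalue of the deflated covariance
    mat P = eye<mat>(r, r);
    if (k > 0) {
      mat Wk = W.cols(0, k - 1);
      P -= Wk * Wk.t();
    }
    vec ev = eig_sym(P * Cz * P);
    if (ev.max() < exhaust_tol) break;

    vec w = W0.col(c);
    if (k > 0) {
      mat Wk = W.cols(0, k - 1);
      w -= Wk * (Wk.t() * w);
    }
    double nrm = norm(w);
    if (nrm < 1e-12) break;          // initial direction fully consumed
    w /= nrm;

    bool ok = false;
    int it = 0;
    for (; it < max_iter; ++it) {
      vec u = Z.t() * w;             // p-vector of projections
      vec g = tanh(u);
      double gp = 1.0 - mean(square(g));   // mean of g'(u) = 1 - tanh^2
      vec w1 = (Z * g) / p - gp * w;
      if (k > 0) {
        mat Wk = W.cols(0, k - 1);
        w1 -= Wk * (Wk.t() * w1);
      }
      nrm = norm(w1);
      if (nrm < 1e-12) { it = max_iter; break; }  // degenerate, treat as capped
      w1 /= nrm;
      double d = std::abs(dot(w1, w));
      w = w1;
      if (d > 1.0 - tol) { ok = true; ++it; break; }
    }
    W.col(k) = w;
    conv.push_back(ok ? 1 : 0);
    iters.push_back(it);
    ++k;
  }

  mat Wout = (k > 0) ? mat(W.cols(0, k - 1)) : mat(r, 0);
  return Rcpp::List::create(
    Rcpp::Named("W") = Wout,
    Rcpp::Named("converged") = conv,
    Rcpp::Named("iterations") = iters);
}
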