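// Inner alternating NIPALS loop with rank-based soft-thresholding.
// Mirrors the semantics of the exported R primitive soft_threshold_k():
// lambda is the (keep+1)-th largest magnitude, survivors shrink by lambda,
// boundary ties are admitted in ascending index order and shrink to zero.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// In-place threshold; returns true when a boundary tie shrank a survivor
// to zero (result sparser than requested).
static bool soft_threshold_inplace(arma::vec& v, const int keep) {
  const int m = v.n_elem;
  arma::vec a = arma::abs(v);
  if (a.max() == 0.0) {
    v.zeros();
    return false;
  }
  double lambda = 0.0;
  if (keep < m) {
    arma::vec s = a;
    std::nth_element(s.begin(), s.begin() + (m - 1 - keep), s.end());
    lambda = s[m - 1 - keep];
  }
  int cnt = 0;
  for (int i = 0; i < m; ++i) {
    if (a[i] > lambda) {
      v[i] = (v[i] > 0 ? 1.0 : -1.0) * (a[i] - lambda);
      ++cnt;
    } else {
      v[i] = 0.0;
    }
  }
  return (cnt < keep) && (lambda > 0.0);
}

// Pearson correlation; returns NA when either argument has no variance.
static double pearson(const arma::vec& a, const arma::vec& b) {
  const arma::vec da = a - arma::mean(a);
  const arma::vec db = b - arma::mean(b);
  const double va = arma::dot(da, da);
  const double vb = arma::dot(db, db);
  if (va == 0.0 || vb == 0.0) return NA_REAL;
  return arma::dot(da, db) / std::sqrt(va * vb);
}

// [[Rcpp::export]]
List nipals_core(const arma::mat& x1, const arma::mat& x2,
                 const int p_alpha, const int q_beta,
                 const arma::vec& init, const double tol,
                 const int max_iter) {
  const int n = x1.n_rows;
  const int p = x1.n_cols;
  const int q = x2.n_cols;

  arma::vec alpha(p, arma::fill::zeros);
  arma::vec beta(q, arma::fill::zeros);
  arma::vec zeta(n, arma::fill::zeros);
  bool degenerate = false, converged = false, tie_a = false, tie_b = false;
  int t = 0;
  std::vector<double> trace;

  arma::vec gamma = x1 * init;
  double ng = arma::norm(gamma);
  if (ng == 0.0) {
    degenerate = true;
  } else {
    gamma /= ng;
  }

  double rho_prev = 0.0;
  while (!degenerate && t < max_iter) {
    ++t;
    beta = x2.t() * gamma;
    tie_b = soft_threshold_inplace(beta, q_beta) || tie_b;
    if (!arma::any(beta != 0.0)) { degenerate = true; break; }
    zeta = x2 * beta;
    const double nz = arma::norm(zeta);
    if (nz > 0.0) zeta /= nz;

    alpha = x1.t() * zeta;
    tie_a = soft_threshold_inplace(alpha, p_alpha) || tie_a;
    if (!arma::any(alpha != 0.0)) { degenerate = true; break; }
    gamma = x1 * alpha;
    const double ngam = arma::norm(gamma);
    if (ngam > 0.0) gamma /= ngam;

    const double rho = pearson(gamma, zeta);
    if (!arma::is_finite(rho)) { degenerate = true; break; }
    trace.push_back(rho);
    if (std::fabs(rho - rho_prev) <= tol) { converged = true; break; }
    rho_prev = rho;
  }

  return List::create(
    Named("alpha") = NumericVector(alpha.begin(), alpha.end()),
    Named("beta") = NumericVector(beta.begin(), beta.end()),
    Named("gamma") = NumericVector(gamma.begin(), gamma.end()),
    Named("zeta") = NumericVector(zeta.begin(), zeta.end()),
    Named("n_iter") = t,
    Named("converged") = converged,
    Named("degenerate") = degenerate,
    Named("tie_alpha") = tie_a,
    Named("tie_beta") = tie_b,
    Named("rho_trace") = NumericVector(trace.begin(), trace.end()));
}
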