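// Leave-one-out LDA held-out probabilities.
//
// Hot loop of the nested cross-validation engine: for each subject i the
// classifier is refit on the remaining n - 1 rows (optionally z-scoring
// features by training-fold statistics) and the held-out posterior of
// the positive class recorded.  Mirrors the reference R implementation
// (.lda_fit / .lda_prob) exactly; a unit test pins the two paths
// together.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::NumericVector lda_loocv_probs_cpp(const arma::mat& X,
                                        const arma::uvec& y01,
                                        const double shrinkage,
                                        const bool standardize) {
  const uword n = X.n_rows, p = X.n_cols;
  Rcpp::NumericVector out(n, NA_REAL);

  for (uword i = 0; i < n; ++i) {
    // training fold = all rows but i
    uvec idx(n - 1);
    uword k = 0;
    for (uword j = 0; j < n; ++j) if (j != i) idx(k++) = j;
    mat Xtr = X.rows(idx);
    uvec ytr = y01(idx);

    const uword n1 = accu(ytr), n0 = (n - 1) - n1;
    if (n1 == 0 || n0 == 0) continue;  // degenerate fold: leave NA

    rowvec xi = X.row(i);
    if (standardize) {
      rowvec ctr = mean(Xtr, 0);
      rowvec scl = stddev(Xtr, 0, 0);  // divisor n - 1
      for (uword c = 0; c < p; ++c) {
        if (!std::isfinite(scl(c)) || scl(c) == 0.0) scl(c) = 1.0;
      }
      Xtr.each_row() -= ctr;
      Xtr.each_row() /= scl;
      xi = (xi - ctr) / scl;
    }

    rowvec mu1(p, fill::zeros), mu0(p, fill::zeros);
    for (uword r = 0; r < Xtr.n_rows; ++r) {
      if (ytr(r)) mu1 += Xtr.row(r); else mu0 += Xtr.row(r);
    }
    mu1 /= (double)n1;
    mu0 /= (double)n0;

    mat S(p, p, fill::zeros);
    for (uword r = 0; r < Xtr.n_rows; ++r) {
      rowvec d = Xtr.row(r) - (ytr(r) ? mu1 : mu0);
      S += d.t() * d;
    }
    S /= (double)(n1 + n0 - 2);
    double eps = shrinkage * trace(S) / (double)p;
    if (eps < 1e-300) eps = 1e-300;
    S.diag() += eps;

    vec a = solve(S, (mu1 - mu0).t(), solve_opts::likely_sympd);
    double b = -0.5 * dot(mu1 + mu0, a) +
      std::log((double)n1 / (double)n0);
    double z = dot(xi, a) + b;
    out[i] = 1.0 / (1.0 + std::exp(-z));
  }
  return out;
}
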