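// Profiled REML objective for the per-protein mixed model, evaluated via
// the Woodbury identity on precomputed weighted cross-products. Called many
// times per protein from the variance-ratio optimizer, hence compiled.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Returns c(objective, quadratic form). On a failed factorization the
// objective is 1e300 and the quadratic form NA.
// [[Rcpp::export]]
Rcpp::NumericVector reml_eval_cpp(const arma::mat& XtWX, const arma::mat& UtWX,
                                  const arma::mat& UtWU, const arma::vec& XtWy,
                                  const arma::vec& UtWy, double ytWy,
                                  double sum_log_w, int n, int p,
                                  const arma::ivec& block_sizes,
                                  const arma::vec& gamma) {
  const double fail = 1e300;
  Rcpp::NumericVector bad =
      Rcpp::NumericVector::create(fail, NA_REAL);
  uword q = UtWU.n_rows;

  double logdetV = -sum_log_w;
  mat XtViX = XtWX;
  vec XtViy = XtWy;
  double ytViy = ytWy;

  if (q > 0) {
    vec s(q);
    uword off = 0;
    for (uword b = 0; b < block_sizes.n_elem; ++b) {
      uword qb = (uword)block_sizes[b];
      s.subvec(off, off + qb - 1).fill(std::sqrt(gamma[b]));
      off += qb;
    }
    mat M = eye<mat>(q, q) + (s * s.t()) % UtWU;  // I + S U'WU S
    mat Rm;
    if (!chol(Rm, M)) return bad;
    logdetV += 2.0 * accu(log(Rm.diag()));
    // stack the p fixed columns and y into one solve
    mat A(q, (uword)p + 1);
    if (p > 0) A.cols(0, p - 1) = UtWX.each_col() % s;
    A.col(p) = UtWy % s;
    mat MiA = solve(trimatu(Rm), solve(trimatl(Rm.t()), A));
    mat G = A.t() * MiA;  // (p+1) x (p+1)
    if (p > 0) {
      XtViX -= G.submat(0, 0, p - 1, p - 1);
      XtViy -= G.submat(0, p, p - 1, p).col(0);
    }
    ytViy -= G(p, p);
  }

  double logdetX = 0.0, quad;
  if (p > 0) {
    mat Rx;
    if (!chol(Rx, XtViX)) return bad;
    logdetX = 2.0 * accu(log(Rx.diag()));
    vec beta = solve(trimatu(Rx), solve(trimatl(Rx.t()), XtViy));
    quad = ytViy - dot(XtViy, beta);
  } else {
    quad = ytViy;
  }
  if (quad < 1e-300) quad = 1e-300;
  double obj = logdetV + logdetX + (n - p) * std::log(quad);
  return Rcpp::NumericVector::create(obj, quad);
}
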