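// Tukey median polish with missing cells, row sweep first. The iteration
// mirrors the documented contract of median_polish() in R/summarize.R; it is
// compiled because protein summarization polishes one small matrix per
// protein and run.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// median over finite values; R convention (mean of the two central values
// for an even count); returns NA when no finite value is present
static double na_median(std::vector<double>& v) {
  if (v.empty()) return NA_REAL;
  size_t n = v.size();
  std::sort(v.begin(), v.end());
  if (n % 2 == 1) return v[n / 2];
  return (v[n / 2 - 1] + v[n / 2]) / 2.0;
}

// [[Rcpp::export]]
List median_polish_cpp(NumericMatrix x, double tol, int max_iter) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix z(clone(x));
  NumericVector r(nr), c(nc);
  double t0 = 0.0;

  double scale = 1.0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (R_finite(z(i, j))) scale += std::fabs(z(i, j));

  double oldsum = scale - 1.0;
  bool converged = false;
  int iter = 0;
  std::vector<double> buf;

  while (iter < max_iter) {
    ++iter;
    // row sweep
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int j = 0; j < nc; ++j)
        if (R_finite(z(i, j))) buf.push_back(z(i, j));
      double m = na_median(buf);
      if (!R_finite(m)) continue;
      for (int j = 0; j < nc; ++j)
        if (R_finite(z(i, j))) z(i, j) -= m;
      r[i] += m;
    }
    {
      buf.assign(c.begin(), c.end());
      double m = na_median(buf);
      for (int j = 0; j < nc; ++j) c[j] -= m;
      t0 += m;
    }
    // column sweep
    for (int j = 0; j < nc; ++j) {
      buf.clear();
      for (int i = 0; i < nr; ++i)
        if (R_finite(z(i, j))) buf.push_back(z(i, j));
      double m = na_median(buf);
      if (!R_finite(m)) continue;
      for (int i = 0; i < nr; ++i)
        if (R_finite(z(i, j))) z(i, j) -= m;
      c[j] += m;
    }
    {
      buf.assign(r.begin(), r.end());
      double m = na_median(buf);
      for (int i = 0; i < nr; ++i) r[i] -= m;
      t0 += m;
    }
    double newsum = 0.0;
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i)
        if (R_finite(z(i, j))) newsum += std::fabs(z(i, j));
    if (std::fabs(newsum - oldsum) < tol * scale) {
      converged = true;
      break;
    }
    oldsum = newsum;
  }
  return List::create(_["overall"] = t0, _["row_effects"] = r,
                      _["col_effects"] = c, _["residuals"] = z,
                      _["iterations"] = iter, _["converged"] = converged);
}
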