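#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact least-absolute-deviation (tau = 0.5 quantile) simple regression.
// An optimal L1 line with intercept always attains its minimum at one of the
// candidate slopes defined by pairs of points with distinct x: the profile
// loss min_a sum |y - a - b x| is piecewise linear in b with breakpoints at
// exactly those pairwise slopes. For each candidate slope the optimal
// intercept is the median of the residuals y - b x. Ties in the minimal loss
// are broken toward the smallest |slope|, then the smallest slope, so the fit
// is deterministic and an outlier cannot drag the fit off a flat optimum.
static double median_inplace(std::vector<double>& v) {
  const size_t n = v.size();
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double hi = v[h];
  if (n % 2 == 1) return hi;
  std::nth_element(v.begin(), v.begin() + h - 1, v.begin() + h);
  return 0.5 * (v[h - 1] + hi);
}

// [[Rcpp::export(name = ".l1_line_fit")]]
NumericVector l1_line_fit(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n < 2 || y.size() != n) stop("l1 fit needs matched vectors of length >= 2");

  std::vector<double> slopes;
  slopes.reserve((size_t)n * (n - 1) / 2 + 1);
  slopes.push_back(0.0);  // horizontal line is always a candidate
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (x[i] != x[j]) slopes.push_back((y[j] - y[i]) / (x[j] - x[i]));
  std::sort(slopes.begin(), slopes.end());
  slopes.erase(std::unique(slopes.begin(), slopes.end()), slopes.end());

  double best_loss = R_PosInf, best_a = NA_REAL, best_b = NA_REAL;
  std::vector<double> resid(n);
  for (double b : slopes) {
    for (int i = 0; i < n; ++i) resid[i] = y[i] - b * x[i];
    std::vector<double> tmp(resid);
    double a = median_inplace(tmp);
    double loss = 0.0;
    for (int i = 0; i < n; ++i) loss += std::fabs(resid[i] - a);
    bool first = !R_FINITE(best_loss);
    double tol = first ? 0.0 : 1e-9 * (1.0 + std::fabs(best_loss));
    bool better = first || loss < best_loss - tol;
    bool tied = !first && std::fabs(loss - best_loss) <= tol;
    if (better ||
        (tied && (std::fabs(b) < std::fabs(best_b) - 1e-12 ||
                  (std::fabs(std::fabs(b) - std::fabs(best_b)) <= 1e-12 &&
                   b < best_b)))) {
      best_loss = loss;
      best_a = a;
      best_b = b;
    }
  }
  return NumericVector::create(_["intercept"] = best_a, _["slope"] = best_b,
                               _["loss"] = best_loss);
}
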