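#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact permutation p-value for Spearman's rho (two-sided), enumerating all
// distinct arrangements of the y-ranks with std::next_permutation.  Ties are
// assumed mid-ranked by the caller.  Feasible for n <= 10 (10! = 3.6e6).

static double rank_cor(const std::vector<double>& rx,
                       const std::vector<double>& ry) {
  int n = (int)rx.size();
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += rx[i]; my += ry[i]; }
  mx /= n; my /= n;
  double sxy = 0, sxx = 0, syy = 0;
  for (int i = 0; i < n; ++i) {
    double dx = rx[i] - mx, dy = ry[i] - my;
    sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
  }
  if (sxx <= 0 || syy <= 0) return NA_REAL;
  return sxy / std::sqrt(sxx * syy);
}

//' @noRd
// [[Rcpp::export(name = ".spearman_perm_p_cpp")]]
double spearman_perm_p_cpp(NumericVector rank_x, NumericVector rank_y) {
  int n = rank_x.size();
  std::vector<double> rx(rank_x.begin(), rank_x.end());
  std::vector<double> ry(rank_y.begin(), rank_y.end());
  double obs = rank_cor(rx, ry);
  if (!R_finite(obs)) return NA_REAL;
  std::vector<double> perm = ry;
  std::sort(perm.begin(), perm.end());
  long long total = 0, hits = 0;
  const double eps = 1e-12;
  do {
    ++total;
    double r = rank_cor(rx, perm);
    if (R_finite(r) && std::fabs(r) >= std::fabs(obs) - eps) ++hits;
  } while (std::next_permutation(perm.begin(), perm.end()));
  return (double)hits / (double)total;
}
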