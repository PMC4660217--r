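#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Two-sample KS statistic from per-unique-value group counts.
static double ks_stat(const std::vector<int>& c1, const std::vector<int>& c2,
                      int n1, int n2) {
  double d = 0.0, f1 = 0.0, f2 = 0.0;
  size_t m = c1.size();
  for (size_t k = 0; k < m; ++k) {
    f1 += c1[k] / (double)n1;
    f2 += c2[k] / (double)n2;
    double a = std::fabs(f1 - f2);
    if (a > d) d = a;
  }
  return d;
}

// Bootstrap KS test: resample the pooled sample with replacement into groups
// of the original sizes; count bootstrap statistics >= observed. max_exceed
// allows early exit once the count proves p above a threshold of interest
// (used inside permutation grids); max_exceed <= 0 disables it.
// [[Rcpp::export]]
List cpp_ks_boot(NumericVector x, NumericVector y, int n_boot, int max_exceed) {
  RNGScope scope;
  int n1 = x.size(), n2 = y.size(), n = n1 + n2;
  std::vector<double> pooled(n);
  for (int i = 0; i < n1; ++i) pooled[i] = x[i];
  for (int i = 0; i < n2; ++i) pooled[n1 + i] = y[i];
  std::vector<double> sorted(pooled);
  std::sort(sorted.begin(), sorted.end());
  std::vector<double> uniq;
  uniq.reserve(n);
  for (int i = 0; i < n; ++i)
    if (i == 0 || sorted[i] != sorted[i - 1]) uniq.push_back(sorted[i]);
  int m = uniq.size();
  // map each pooled item to its unique-value index
  std::vector<int> uid(n);
  for (int i = 0; i < n; ++i)
    uid[i] = std::lower_bound(uniq.begin(), uniq.end(), pooled[i]) - uniq.begin();
  // resampling draws map through the *sorted* pooled array so that the
  // bootstrap stream is invariant to the order (and exchange) of the inputs
  std::vector<int> uid_sorted(n);
  for (int i = 0; i < n; ++i)
    uid_sorted[i] = std::lower_bound(uniq.begin(), uniq.end(), sorted[i]) - uniq.begin();

  std::vector<int> c1(m, 0), c2(m, 0);
  for (int i = 0; i < n1; ++i) c1[uid[i]]++;
  for (int i = 0; i < n2; ++i) c2[uid[n1 + i]]++;
  double d_obs = ks_stat(c1, c2, n1, n2);

  int exceed = 0, done = 0;
  const double eps = 1e-12;
  for (int b = 0; b < n_boot; ++b) {
    std::fill(c1.begin(), c1.end(), 0);
    std::fill(c2.begin(), c2.end(), 0);
    for (int i = 0; i < n1; ++i) {
      int t = (int)std::floor(unif_rand() * n);
      if (t >= n) t = n - 1;
      c1[uid_sorted[t]]++;
    }
    for (int i = 0; i < n2; ++i) {
      int t = (int)std::floor(unif_rand() * n);
      if (t >= n) t = n - 1;
      c2[uid_sorted[t]]++;
    }
    if (ks_stat(c1, c2, n1, n2) >= d_obs - eps) ++exceed;
    ++done;
    if (max_exceed > 0 && exceed >= max_exceed) break;
  }
  return List::create(_["statistic"] = d_obs, _["exceed"] = exceed,
                      _["completed"] = done);
}
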