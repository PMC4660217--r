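#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Copula (probability-integral) transform via average ranks. Ranks are kept
// on the half-integer grid 2*rank so that pairwise differences index a
// precomputed kernel table exactly, ties included.
static std::vector<int> rank2x(const NumericVector& x) {
  int n = x.size();
  std::vector<int> ord(n), r2(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return x[a] < x[b]; });
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[ord[j + 1]] == x[ord[i]]) ++j;
    int avg2 = i + j + 2;  // 2 * average 1-based rank
    for (int k = i; k <= j; ++k) r2[ord[k]] = avg2;
    i = j + 1;
  }
  return r2;
}

// Kernel lookup: Kt[d] = exp(-(d / (2(n+1)))^2 / (2 h^2)) for d = 0..2n.
static std::vector<double> kernel_table(int n, double h) {
  std::vector<double> kt(2 * n + 1);
  double denom = 2.0 * (n + 1.0);
  double inv2h2 = 1.0 / (2.0 * h * h);
  for (int d = 0; d <= 2 * n; ++d) {
    double u = d / denom;
    kt[d] = std::exp(-u * u * inv2h2);
  }
  return kt;
}

static double mi_from_ranks(const std::vector<int>& rx, const std::vector<int>& ry,
                            const std::vector<double>& kt, int n) {
  double mi = 0.0;
  for (int i = 0; i < n; ++i) {
    double sj = 0.0, sx = 0.0, sy = 0.0;
    int rxi = rx[i], ryi = ry[i];
    for (int j = 0; j < n; ++j) {
      double kx = kt[std::abs(rxi - rx[j])];
      double ky = kt[std::abs(ryi - ry[j])];
      sj += kx * ky;
      sx += kx;
      sy += ky;
    }
    mi += std::log(n * sj / (sx * sy));
  }
  mi /= n;
  return mi > 0.0 ? mi : 0.0;
}

// [[Rcpp::export]]
double cpp_mutual_information(NumericVector x, NumericVector y, double h) {
  int n = x.size();
  std::vector<int> rx = rank2x(x), ry = rank2x(y);
  std::vector<double> kt = kernel_table(n, h);
  return mi_from_ranks(rx, ry, kt, n);
}

// MI of one hub profile against every row of a (genes x samples) matrix.
// [[Rcpp::export]]
NumericVector cpp_mi_hub(NumericVector hub, NumericMatrix mat, double h) {
  int n = hub.size(), g = mat.nrow();
  std::vector<int> rh = rank2x(hub);
  std::vector<double> kt = kernel_table(n, h);
  NumericVector out(g);
  NumericVector row(n);
  for (int r = 0; r < g; ++r) {
    for (int j = 0; j < n; ++j) row[j] = mat(r, j);
    std::vector<int> rg = rank2x(row);
    out[r] = mi_from_ranks(rh, rg, kt, n);
  }
  return out;
}

// Null MI pool: MI between a fixed rank grid and independently permuted
// ranks (copula null of independence). Uses R's RNG so set.seed() applies.
// [[Rcpp::export]]
NumericVector cpp_null_mi(int n, int n_null, double h) {
  RNGScope scope;
  std::vector<double> kt = kernel_table(n, h);
  // marginal kernel sums depend on rank position only (no ties in the null)
  std::vector<double> marg(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += kt[2 * std::abs(i - j)];
    marg[i] = s;
  }
  std::vector<int> perm(n);
  NumericVector out(n_null);
  for (int b = 0; b < n_null; ++b) {
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) {  // Fisher-Yates
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    double mi = 0.0;
    for (int i = 0; i < n; ++i) {
      double sj = 0.0;
      int pi = perm[i];
      for (int j = 0; j < n; ++j)
        sj += kt[2 * std::abs(i - j)] * kt[2 * std::abs(pi - perm[j])];
      mi += std::log(n * sj / (marg[i] * marg[pi]));
    }
    mi /= n;
    out[b] = mi > 0.0 ? mi : 0.0;
  }
  return out;
}
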