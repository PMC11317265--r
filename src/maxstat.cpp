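#include <Rcpp.h>
using namespace Rcpp;

// Standardized two-group log-rank statistic (O - E) / sqrt(V) for group 1,
// hypergeometric variance, deaths-precede-censorings at tied times.
// time must be sorted ascending; event and g are aligned with it.
static double lr_standardized(const NumericVector& time,
                              const IntegerVector& event,
                              const std::vector<int>& g) {
  const int n = time.size();
  double n_risk = n, n1_risk = 0.0;
  for (int i = 0; i < n; ++i) n1_risk += g[i];
  double U = 0.0, V = 0.0;
  int i = 0;
  while (i < n) {
    int j = i;
    int d = 0, d1 = 0, rem1 = 0;
    while (j < n && time[j] == time[i]) {
      if (event[j] == 1) { ++d; d1 += g[j]; }
      rem1 += g[j];
      ++j;
    }
    if (d > 0 && n_risk > 1) {
      const double p1 = n1_risk / n_risk;
      U += d1 - d * p1;
      V += d * p1 * (1.0 - p1) * (n_risk - d) / (n_risk - 1.0);
    }
    n_risk -= (j - i);
    n1_risk -= rem1;
    i = j;
  }
  if (V <= 0.0) return 0.0;
  return U / std::sqrt(V);
}

// Standardized log-rank statistic at every candidate cutpoint of x
// (group 1 = x > cut). time sorted ascending; x aligned with it.
// [[Rcpp::export]]
NumericVector cpp_maxstat_scan(NumericVector x, NumericVector time,
                               IntegerVector event, NumericVector cuts) {
  const int n = x.size(), k = cuts.size();
  NumericVector stats(k);
  std::vector<int> g(n);
  for (int c = 0; c < k; ++c) {
    for (int i = 0; i < n; ++i) g[i] = x[i] > cuts[c] ? 1 : 0;
    stats[c] = lr_standardized(time, event, g);
  }
  return stats;
}

// Permutation reference distribution of M = max_c |standardized statistic|,
// permuting x across subjects. Uses R's RNG (seed controlled from R).
// Returns the count of permutations with M_perm >= m_obs - 1e-12.
// [[Rcpp::export]]
int cpp_maxstat_perm_count(NumericVector x, NumericVector time,
                           IntegerVector event, NumericVector cuts,
                           int n_perm, double m_obs) {
  const int n = x.size(), k = cuts.size();
  int count = 0;
  NumericVector xp(n);
  std::vector<int> g(n);
  for (int b = 0; b < n_perm; ++b) {
    IntegerVector idx = Rcpp::sample(n, n, false) - 1;
    for (int i = 0; i < n; ++i) xp[i] = x[idx[i]];
    double m = 0.0;
    for (int c = 0; c < k; ++c) {
      for (int i = 0; i < n; ++i) g[i] = xp[i] > cuts[c] ? 1 : 0;
      const double s = std::fabs(lr_standardized(time, event, g));
      if (s > m) m = s;
    }
    if (m >= m_obs - 1e-12) ++count;
  }
  return count;
}
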