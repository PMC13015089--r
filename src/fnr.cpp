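#include "epsmatch.h"
using namespace Rcpp;

// Error-configuration model: e error columns among l alignment columns cut
// the alignment into e + 1 error-free runs; a run of length g preserves
// max(0, g - k + 1) ungapped k-mer windows.  The DP runs over
// (run index, error-free columns used, surviving-window budget capped at t)
// and counts configurations by the bijection between e-subsets of columns
// and weak compositions of l - e into e + 1 runs.

static double choose_d(int n, int k) { return ::Rf_choose((double)n, (double)k); }

// Counts of configurations by surviving k-mer count s for s = 0..t-1,
// with the final slot holding the count for s >= t.
// [[Rcpp::export]]
NumericVector cpp_fnr_counts(int l, int e, int k, int t) {
  const int ncols = l - e;
  NumericVector out(t + 1);
  if (t == 0) {
    out[0] = choose_d(l, e);
    return out;
  }
  // f[c][s]: configurations over the runs placed so far using c columns,
  // with survivor count min(s, t)
  std::vector<std::vector<double>> f(ncols + 1,
                                     std::vector<double>(t + 1, 0.0));
  f[0][0] = 1.0;
  for (int run = 0; run < e + 1; ++run) {
    std::vector<std::vector<double>> g(ncols + 1,
                                       std::vector<double>(t + 1, 0.0));
    for (int c = 0; c <= ncols; ++c)
      for (int s = 0; s <= t; ++s) {
        const double v = f[c][s];
        if (v == 0.0) continue;
        for (int add = 0; add + c <= ncols; ++add) {
          const int surv = add - k + 1;
          const int s2 = std::min(t, s + (surv > 0 ? surv : 0));
          g[c + add][s2] += v;
        }
      }
    f.swap(g);
  }
  for (int s = 0; s <= t; ++s) out[s] = f[ncols][s];
  return out;
}

// [[Rcpp::export]]
double cpp_fnr_dp(int l, int e, int k, int t) {
  if (t <= 0) return 0.0;
  NumericVector cnt = cpp_fnr_counts(l, e, k, t);
  double bad = 0.0;
  for (int s = 0; s < t; ++s) bad += cnt[s];
  return bad / choose_d(l, e);
}

// Brute-force enumeration over all C(l, e) error-column subsets.
// [[Rcpp::export]]
double cpp_fnr_enum(int l, int e, int k, int t) {
  if (t <= 0) return 0.0;
  if (e == 0) return (l - k + 1 < t) ? 1.0 : 0.0;
  std::vector<int> idx(e);
  for (int i = 0; i < e; ++i) idx[i] = i;
  double bad = 0.0, total = 0.0;
  while (true) {
    // survivors from runs between error columns
    int surv = 0, prev = -1;
    for (int i = 0; i < e; ++i) {
      const int g = idx[i] - prev - 1;
      if (g >= k) surv += g - k + 1;
      prev = idx[i];
    }
    const int g = l - prev - 1;
    if (g >= k) surv += g - k + 1;
    total += 1.0;
    if (surv < t) bad += 1.0;
    // next combination
    int i = e - 1;
    while (i >= 0 && idx[i] == l - e + i) --i;
    if (i < 0) break;
    ++idx[i];
    for (int j = i + 1; j < e; ++j) idx[j] = idx[j - 1] + 1;
  }
  return bad / total;
}

// Minimum surviving k-mer count over all configurations (used to check the
// counting lemma is a valid lower bound on small cases).
// [[Rcpp::export]]
int cpp_min_survivors(int l, int e, int k) {
  if (e == 0) return std::max(0, l - k + 1);
  std::vector<int> idx(e);
  for (int i = 0; i < e; ++i) idx[i] = i;
  int best = INT_MAX;
  while (true) {
    int surv = 0, prev = -1;
    for (int i = 0; i < e; ++i) {
      const int g = idx[i] - prev - 1;
      if (g >= k) surv += g - k + 1;
      prev = idx[i];
    }
    const int g = l - prev - 1;
    if (g >= k) surv += g - k + 1;
    best = std::min(best, surv);
    int i = e - 1;
    while (i >= 0 && idx[i] == l - e + i) --i;
    if (i < 0) break;
    ++idx[i];
    for (int j = i + 1; j < e; ++j) idx[j] = idx[j - 1] + 1;
  }
  return best;
}
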