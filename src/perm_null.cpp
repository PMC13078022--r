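#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Walker/Vose alias table for O(1) draws with probability proportional to
// freq. Drawing without replacement is done by rejection: redraw while the
// item is already in the current set, which is exactly successive (PPS)
// sampling -- each accepted draw is distributed proportionally to the
// weights of the remaining items. Rejection is cheap because individual
// inclusion probabilities are small relative to the pool.
struct AliasTable {
  std::vector<double> prob;
  std::vector<int> alias;
  int n;
  explicit AliasTable(const NumericVector& freq) {
    n = freq.size();
    prob.resize(n);
    alias.resize(n);
    double total = 0.0;
    for (int i = 0; i < n; ++i) total += freq[i];
    std::vector<double> scaled(n);
    std::vector<int> small, large;
    small.reserve(n);
    large.reserve(n);
    for (int i = 0; i < n; ++i) {
      scaled[i] = freq[i] * n / total;
      (scaled[i] < 1.0 ? small : large).push_back(i);
    }
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = scaled[s];
      alias[s] = l;
      scaled[l] = (scaled[l] + scaled[s]) - 1.0;
      (scaled[l] < 1.0 ? small : large).push_back(l);
    }
    while (!large.empty()) { prob[large.back()] = 1.0; large.pop_back(); }
    while (!small.empty()) { prob[small.back()] = 1.0; small.pop_back(); }
  }
  inline int draw() const {
    double u = unif_rand() * n;
    int i = static_cast<int>(u);
    if (i >= n) i = n - 1; // guard against u == n after rounding
    return (u - i) < prob[i] ? i : alias[i];
  }
};

// Null distribution of the clonality score for one biopsy pair: each
// replicate redraws variant sets of the observed sizes from the cohort pool
// with probability proportional to cohort frequency (without replacement
// within a replicate) and rescores. Uses R's RNG stream, so results are
// reproducible under set.seed().
//
// freq: sampling probabilities (cohort variant frequencies), length = pool
// w:    scoring weights (-log10 frequency), same length/order as freq
// [[Rcpp::export(rng = false)]]
NumericVector perm_null_scores_cpp(int n_a, int n_b, NumericVector freq,
                                   NumericVector w, int n_perm) {
  const int n = freq.size();
  if (n_a > n || n_b > n)
    stop("pool smaller than a profile: cannot draw without replacement");
  AliasTable tab(freq);
  NumericVector out(n_perm);
  std::vector<int> set_a(n_a), set_b(n_b);
  std::vector<int> stamp_a(n, -1), stamp_b(n, -1);
  GetRNGstate();
  for (int p = 0; p < n_perm; ++p) {
    double wa = 0.0, wb = 0.0, shared = 0.0;
    for (int k = 0; k < n_a; ++k) {
      int i = tab.draw();
      while (stamp_a[i] == p) i = tab.draw();
      stamp_a[i] = p;
      set_a[k] = i;
      wa += w[i];
    }
    for (int k = 0; k < n_b; ++k) {
      int i = tab.draw();
      while (stamp_b[i] == p) i = tab.draw();
      stamp_b[i] = p;
      set_b[k] = i;
      wb += w[i];
      if (stamp_a[i] == p) shared += w[i];
    }
    out[p] = shared > 0.0 ? shared / std::sqrt(wa * wb) : 0.0;
  }
  PutRNGstate();
  return out;
}
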