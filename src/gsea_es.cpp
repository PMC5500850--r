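#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Weighted Kolmogorov-Smirnov running-sum enrichment score for a gene set
// against a ranked profile, evaluated only at the candidate extremes
// (just before / just after each hit), which is where the running sum
// attains its maximal deviation.
//
// w_abs: |metric|^p for the profile genes in ranked (descending) order.
// hits:  0-based positions of the set members in that ranked order,
//        strictly increasing.
static double es_from_hits(const NumericVector &w_abs,
                           const std::vector<int> &hits) {
  const int n = w_abs.size();
  const int k = (int)hits.size();
  double nr = 0.0;
  for (int j = 0; j < k; j++) nr += w_abs[hits[j]];
  const double miss = 1.0 / (double)(n - k);
  double best = 0.0, run_hit = 0.0;
  // a set whose members all carry zero weight shows no enrichment
  // signal in either direction
  if (nr <= 0.0) return 0.0;
  for (int j = 0; j < k; j++) {
    double before = run_hit - (hits[j] - j) * miss;
    run_hit += w_abs[hits[j]] / nr;
    double after = run_hit - (hits[j] - j) * miss;
    if (std::fabs(before) > std::fabs(best)) best = before;
    if (std::fabs(after) > std::fabs(best)) best = after;
  }
  return best;
}

// [[Rcpp::export(name = ".gsea_es_cpp")]]
double gsea_es_cpp(NumericVector w_abs, IntegerVector hits1) {
  std::vector<int> hits(hits1.size());
  for (int j = 0; j < hits1.size(); j++) hits[j] = hits1[j] - 1;
  std::sort(hits.begin(), hits.end());
  return es_from_hits(w_abs, hits);
}

// Null enrichment scores for random gene sets of size k drawn without
// replacement from the n ranked genes. Uses R's RNG.
// [[Rcpp::export(name = ".gsea_null_es_cpp")]]
NumericVector gsea_null_es_cpp(NumericVector w_abs, int k, int n_perm) {
  const int n = w_abs.size();
  if (k >= n) stop("set size must be smaller than the profile");
  NumericVector out(n_perm);
  std::vector<int> hits(k);
  std::vector<bool> used(n, false);
  for (int b = 0; b < n_perm; b++) {
    int filled = 0;
    while (filled < k) {
      int idx = (int)(unif_rand() * n);
      if (idx == n) idx = n - 1;
      if (!used[idx]) {
        used[idx] = true;
        hits[filled++] = idx;
      }
    }
    std::sort(hits.begin(), hits.end());
    out[b] = es_from_hits(w_abs, hits);
    for (int j = 0; j < k; j++) used[hits[j]] = false;
  }
  return out;
}
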