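#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Draw configurations from the Ewens sampling formula conditioned on the
// number of types k, by sampling uniform random permutations of [n] with
// exactly k cycles and returning their cycle types.  The probability of a
// cycle type (n_1, ..., n_k) among such permutations is
//   #perms with that type / |S_n^k| = n! / (|S_n^k| prod n_i prod m_j!),
// the unordered ESF configuration law given (n, k).
//
// Permutations are built by sequential insertion: element t+1 either opens
// a new cycle or joins the cycle of a uniformly chosen already-placed
// element.  p_new is the (n-1) x k matrix of exact new-cycle
// probabilities, p_new(t, j) = P(element t+1 opens a cycle | t placed,
// j cycles so far), precomputed in R from the Stirling-style
// completion-count table (see new_cycle_probs()).
//
// Returns, per draw, sum(log n_i) -- the only configuration-dependent part
// of the ordered ESF log-probability -- and optionally the configurations.
// [[Rcpp::export]]
List sample_configs_ck_cpp(int n, int k, NumericMatrix p_new, int draws,
                           bool keep_configs) {
  NumericVector sumlog(draws);
  List configs(keep_configs ? draws : 0);
  std::vector<int> cycle_of(n);
  std::vector<int> sizes(k);
  const double *P = &p_new(0, 0);
  const int stride = p_new.nrow();  // n - 1

  for (int d = 0; d < draws; ++d) {
    int j = 1;
    cycle_of[0] = 0;
    for (int t = 1; t < n; ++t) {
      // state: t elements placed, j cycles; place element t+1
      if (unif_rand() < P[(j - 1) * stride + (t - 1)]) {
        cycle_of[t] = j++;
      } else {
        int r = (int)(unif_rand() * t);
        if (r == t) r--;
        cycle_of[t] = cycle_of[r];
      }
    }
    std::fill(sizes.begin(), sizes.end(), 0);
    for (int t = 0; t < n; ++t) sizes[cycle_of[t]]++;
    double s = 0.0;
    for (int c = 0; c < k; ++c) s += std::log((double)sizes[c]);
    sumlog[d] = s;
    if (keep_configs) {
      std::vector<int> cfg(sizes);
      std::sort(cfg.begin(), cfg.end(), std::greater<int>());
      configs[d] = IntegerVector(cfg.begin(), cfg.end());
    }
  }
  return List::create(_["sumlog"] = sumlog, _["configs"] = configs);
}
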