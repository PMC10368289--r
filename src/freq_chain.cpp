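#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Frequency-table chain: the exact reduction of the agent model when the
// copy pool is the whole previous population ("ALL"), including the
// Wright-Fisher limit p_death = 1.  Each step: per-type binomial deaths,
// then the dead slots are refilled by newborns drawn multinomially from
// the previous counts (weights (n_i/N)^(1+b)), with Bin(D, mu) of them
// innovating fresh labels.
// [[Rcpp::export]]
List run_freq_chain_cpp(IntegerVector labels0, IntegerVector counts0,
                        int next_label, int N, double mu, double p_death,
                        double b, int n_steps, int thin,
                        bool stop_at_fixation) {
  std::vector<int> labels(labels0.begin(), labels0.end());
  std::vector<int> counts(counts0.begin(), counts0.end());
  std::vector<int> dead, born;
  std::vector<double> w;
  std::vector<int> rich_steps, rich_vals;
  const bool biased = (b != 0.0);
  int step = 0;

  for (step = 1; step <= n_steps; ++step) {
    const int k = (int)counts.size();
    int n_dead = 0;
    dead.assign(k, 0);
    if (p_death >= 1.0) {
      dead.assign(counts.begin(), counts.end());
      n_dead = N;
    } else {
      for (int i = 0; i < k; ++i) {
        dead[i] = (int)R::rbinom((double)counts[i], p_death);
        n_dead += dead[i];
      }
    }
    if (n_dead > 0) {
      int n_innov = (mu > 0.0) ? (int)R::rbinom((double)n_dead, mu) : 0;
      int n_copy = n_dead - n_innov;
      born.assign(k, 0);
      if (n_copy > 0) {
        w.resize(k);
        if (biased) {
          for (int i = 0; i < k; ++i)
            w[i] = std::pow((double)counts[i] / N, 1.0 + b);
        } else {
          for (int i = 0; i < k; ++i) w[i] = (double)counts[i];
        }
        double tot = 0.0;
        for (double x : w) tot += x;
        for (double &x : w) x /= tot;
        rmultinom(n_copy, w.data(), k, born.data());
      }
      // apply, dropping extinct types
      size_t out = 0;
      for (int i = 0; i < k; ++i) {
        int c = counts[i] - dead[i] + born[i];
        if (c > 0) {
          counts[out] = c;
          labels[out] = labels[i];
          ++out;
        }
      }
      counts.resize(out);
      labels.resize(out);
      for (int i = 0; i < n_innov; ++i) {
        labels.push_back(next_label++);
        counts.push_back(1);
      }
    }
    if (thin > 0 && (step % thin == 0 || step == n_steps)) {
      rich_steps.push_back(step);
      rich_vals.push_back((int)counts.size());
    }
    if (stop_at_fixation && counts.size() == 1) break;
  }
  if (step > n_steps) step = n_steps;

  return List::create(
    _["labels"] = IntegerVector(labels.begin(), labels.end()),
    _["counts"] = IntegerVector(counts.begin(), counts.end()),
    _["next_label"] = next_label,
    _["richness_step"] = IntegerVector(rich_steps.begin(),
                                       rich_steps.end()),
    _["richness"] = IntegerVector(rich_vals.begin(), rich_vals.end()),
    _["steps_done"] = step);
}
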