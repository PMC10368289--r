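#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// One forward run of the age-structured infinite-alleles model at the
// individual level.  Semantics mirror step_population() in R/population.R:
// the copy pool is a snapshot of the previous step, every individual dies
// independently with probability p_death (equivalently, Bin(N, p_death)
// deaths allocated uniformly), the dead slots are refilled by age-0
// newborns that innovate with probability mu and otherwise copy a role
// model from the pool (frequency-dependent with exponent 1 + b).
//
// c_thresh = -1 encodes "ALL" (whole previous population).  A finite
// c_thresh admits previous-snapshot ages 0..c_thresh-1: ages are measured
// at the moment of copying, after the current step's aging, so the pool
// holds individuals aged 1..c_thresh from the newborns' point of view.
//
// Implementation notes.  Ages are represented implicitly by birth steps
// (slot i was last filled at birth[i]; initial ages map to negative birth
// steps), so aging is free.  For finite c_thresh the pool is maintained
// incrementally -- a flat slot vector with a position index for O(1)
// removal, plus a per-variant count map for the frequency-dependent
// weights -- so one step costs O(deaths + departing cohort), not O(pool).
// Deaths are drawn as D ~ Bin(N, p_death) distinct slots via partial
// Fisher-Yates.  Richness is recorded every `thin` steps (trajectory used
// for the stationarity diagnostic).
// [[Rcpp::export]]
List run_agent_cpp(IntegerVector ages0, IntegerVector variants0,
                   int next_label, int n_steps, double mu, double p_death,
                   int c_thresh, double b, int thin) {
  const int N = ages0.size();
  std::vector<int> variants(variants0.begin(), variants0.end());
  std::vector<int> birth(N);   // birth step of current occupant
  for (int i = 0; i < N; ++i) birth[i] = -ages0[i];

  const bool all_pool = (c_thresh < 0);
  const bool biased = (b != 0.0);

  // incremental pool state (finite pools only)
  std::vector<int> pool_slots;
  std::vector<int> pos;                    // slot -> index in pool_slots
  std::unordered_map<int, int> pool_counts;  // variant -> count in pool
  std::vector<std::vector<int> > ring;     // cohort slot lists by birth
  int ring_len = 0;

  auto pool_add = [&](int slot) {
    pos[slot] = (int)pool_slots.size();
    pool_slots.push_back(slot);
    if (biased) pool_counts[variants[slot]]++;
  };
  auto pool_remove = [&](int slot) {
    int at = pos[slot];
    int last = pool_slots.back();
    pool_slots[at] = last;
    pos[last] = at;
    pool_slots.pop_back();
    pos[slot] = -1;
    if (biased) {
      auto it = pool_counts.find(variants[slot]);
      if (--(it->second) == 0) pool_counts.erase(it);
    }
  };

  if (!all_pool) {
    ring_len = c_thresh + 1;
    ring.resize(ring_len);
    pos.assign(N, -1);
    pool_slots.reserve(N);
    for (int i = 0; i < N; ++i) {
      int bs = birth[i];                   // in [-max_age, 0]
      if (bs > -c_thresh) {                // pool of step 1: ages 0..c-1
        ring[((bs % ring_len) + ring_len) % ring_len].push_back(i);
        pool_add(i);
      }
    }
  }

  std::vector<int> prev_variants;
  if (all_pool) prev_variants.reserve(N);
  std::vector<int> perm(N);
  for (int i = 0; i < N; ++i) perm[i] = i;
  std::vector<int> pool_labels;
  std::vector<double> pool_cum;
  std::vector<int> rich_steps, rich_vals;

  for (int step = 1; step <= n_steps; ++step) {
    // ---- copy pool from the previous step's snapshot ----
    if (all_pool) {
      prev_variants.assign(variants.begin(), variants.end());
    } else if (pool_slots.empty()) {
      stop("empty copy pool: no individual with age (at copying) in "
           "[1, %d] at step %d", c_thresh, step);
    }

    if (biased) {
      pool_labels.clear();
      pool_cum.clear();
      double acc = 0.0;
      if (all_pool) {
        std::unordered_map<int, int> counts;
        for (int v : prev_variants) counts[v]++;
        for (auto &kv : counts) {
          pool_labels.push_back(kv.first);
          acc += std::pow(kv.second / (double)N, 1.0 + b);
          pool_cum.push_back(acc);
        }
      } else {
        const double tot = (double)pool_slots.size();
        for (auto &kv : pool_counts) {
          pool_labels.push_back(kv.first);
          acc += std::pow(kv.second / tot, 1.0 + b);
          pool_cum.push_back(acc);
        }
      }
      for (double &c : pool_cum) c /= acc;
    }

    // newborn variants are drawn against the pre-death snapshot, so draw
    // them before mutating the pool (uniform case reads pool_slots live;
    // removals below would bias it)
    int n_dead = (int)R::rbinom((double)N, p_death);
    for (int i = 0; i < n_dead; ++i) {
      int r = i + (int)(unif_rand() * (N - i));
      if (r >= N) r = N - 1;
      std::swap(perm[i], perm[r]);
    }
    std::vector<int> new_vars(n_dead);
    for (int i = 0; i < n_dead; ++i) {
      if (mu > 0.0 && unif_rand() < mu) {
        new_vars[i] = next_label++;
      } else if (biased) {
        double u = unif_rand();
        int lo = 0, hi = (int)pool_cum.size() - 1;
        while (lo < hi) {
          int mid = (lo + hi) / 2;
          if (pool_cum[mid] < u) lo = mid + 1; else hi = mid;
        }
        new_vars[i] = pool_labels[lo];
      } else if (all_pool) {
        int r = (int)(unif_rand() * N);
        if (r >= N) r = N - 1;
        new_vars[i] = prev_variants[r];
      } else {
        int r = (int)(unif_rand() * pool_slots.size());
        if (r >= (int)pool_slots.size()) r = (int)pool_slots.size() - 1;
        new_vars[i] = variants[pool_slots[r]];
      }
    }

    // ---- apply deaths and births ----
    std::vector<int> *newcoh = nullptr;
    if (!all_pool) {
      newcoh = &ring[((step % ring_len) + ring_len) % ring_len];
      newcoh->clear();
    }
    for (int i = 0; i < n_dead; ++i) {
      int slot = perm[i];
      if (!all_pool) {
        if (pos[slot] >= 0) pool_remove(slot);  // occupant dies
        variants[slot] = new_vars[i];
        birth[slot] = step;
        newcoh->push_back(slot);
        pool_add(slot);                          // newborn joins the pool
      } else {
        variants[slot] = new_vars[i];
        birth[slot] = step;
      }
    }

    // ---- cohort born (step - c_thresh) ages out of the pool ----
    if (!all_pool) {
      int bs = step - c_thresh;
      std::vector<int> &old =
        ring[((bs % ring_len) + ring_len) % ring_len];
      for (int slot : old) {
        if (birth[slot] == bs && pos[slot] >= 0) pool_remove(slot);
      }
      old.clear();
    }

    if (thin > 0 && (step % thin == 0 || step == n_steps)) {
      std::unordered_map<int, int> seen;
      for (int v : variants) seen[v]++;
      rich_steps.push_back(step);
      rich_vals.push_back((int)seen.size());
    }
  }

  IntegerVector ages_out(N);
  for (int i = 0; i < N; ++i) ages_out[i] = n_steps - birth[i];
  return List::create(
    _["ages"] = ages_out,
    _["variants"] = IntegerVector(variants.begin(), variants.end()),
    _["next_label"] = next_label,
    _["richness_step"] = IntegerVector(rich_steps.begin(), rich_steps.end()),
    _["richness"] = IntegerVector(rich_vals.begin(), rich_vals.end()));
}
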