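---
title: "Age-structured cultural transmission and tests of neutrality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-structured cultural transmission and tests of neutrality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agedrift)
```

## The model

`agedrift` simulates cultural transmission in a population of constant
size $N$ whose members carry an age and a variant label.  Each time step:

1. every individual, newborns included, dies independently with
   probability $p_{\mathrm{death}}$; survivors age by one step;
2. exactly as many newborns enter (age 0) as individuals died, so $N$ is
   conserved step by step, not merely in expectation;
3. each newborn innovates with probability $\mu$ (infinite-alleles: the
   new label has never been seen before) and otherwise copies a role
   model drawn from the *copy pool*;
4. the pool is a snapshot of the previous step's population -- deaths
   occurring in the current step never remove a role model.

The pool is controlled by $c_{\mathrm{thresh}}$, the maximum age (at the
moment of copying) of a potential role model.  `"ALL"` admits the whole
previous population; $c_{\mathrm{thresh}} = 1$ admits only the variants
transmitted in the immediately preceding step.  Copying is frequency
dependent with strength $b$:
$$p_i = \frac{(n_i^P / N^P)^{1+b}}{\sum_j (n_j^P/N^P)^{1+b}} (1 - \mu),$$
so $b = 0$ is unbiased (linear) transmission, $b > 0$ conformity and
$b < 0$ anti-conformity.  Setting $p_{\mathrm{death}} = 1$ with an
`"ALL"` pool recovers the Wright-Fisher infinite-alleles model.

### The age convention of the copy pool

Ages in the pool are measured *at the moment of copying*, i.e. after the
current step's aging: a finite pool `c_thresh = c` holds the individuals
whose previous-snapshot age is $0 \dots c-1$.  This is what makes the
'1' scenario "copy only the most recently transmitted variants": each
newborn cohort copies the cohort born one step earlier, so the heritable
lineage is a Wright-Fisher chain of size $\approx N p_{\mathrm{death}}$
-- which is exactly the effective size this scenario exhibits.  Under
the alternative convention (previous-snapshot ages $1 \dots c$) the '1'
scenario splits into two decoupled lineages that alternate in time, its
effective size collapses to $\approx 2 N p_{\mathrm{death}}^2$, and the
known effective sizes of the scenario cannot be reproduced; we therefore
regard that reading as an artifact of snapshot bookkeeping and do not
use it.

### Engines

Three implementations share the same law and are tested against each
other:

* an individual-level compiled loop (`run_agent()`), the only engine for
  finite pools with general $b$ and $\mu$;
* a frequency-table reduction (`run_wright_fisher()` and the `"freq"`
  engine of `run_to_steady_state()`): with an `"ALL"` pool, ages never
  influence the dynamics, so the vector of variant counts is Markov --
  deaths are binomial per type and births multinomial from the previous
  counts.  This is exact, not an approximation, and orders of magnitude
  faster;
* a per-age-cohort biallelic reduction used by `estimate_ne()` (neutral,
  two types): individuals within a cohort are exchangeable, so only the
  per-age type counts need simulating.

## Steady state

The burn-in runs $\min(5/\mu,\; 4 \hat N_e)$ generations (one generation
$= 1/p_{\mathrm{death}}$ steps, floor 200 generations), where
$\hat N_e$ is a coarse effective-size guess for the scenario.  The
$5/\mu$ term covers the high-diversity regime: the initial monomorphic
variant decays under innovation pressure like $e^{-\mu t}$, so after
$5/\mu$ generations it is below $1\%$, well under typical stationary
top-variant frequencies; the $4\hat N_e$ term covers the drift-limited
low-diversity regime.  After the burn-in the richness trajectory over
the last quarter of the run must pass a stationarity check: the
AR(1)-adjusted $t$ statistic of its slope must satisfy $|t| < 2$, or the
fitted net drift must be within the stationary fluctuation scale
($\max(2.5\%$ of mean richness, $2.5\,\mathrm{sd})$ -- without the
practical-equivalence escape, low-diversity populations whose richness
is a small integer would fail the slope test on ordinary stationary
excursions).  Failing runs are extended by half their length up to twice
before a condition of class `"agedrift_nonstationary"` is raised with
the diagnostics attached.

Validation: at $p_{\mathrm{death}} = 1$ the steady-state population
richness matches the Ewens expectation
$\sum_{i<N} \theta/(\theta+i)$ with $\theta = 2N\mu$ (the test suite
checks sampled richness against the coalescent prediction), and the
agent and frequency engines are distributionally indistinguishable.

## The Ewens-Watterson (Slatkin exact) test

Conditional on sample size $n$ and number of types $k$, the neutral
probability of an ordered configuration is
$P(n_1,\dots,n_k \mid n,k) = n!\,/\,(|S_n^k|\, k!\, n_1 \cdots n_k)$
with $|S_n^k|$ the unsigned Stirling number of the first kind, computed
here entirely in log space by the standard recurrence.  The tail
probability $P_E$ sums the probabilities of all configurations no more
probable than the observed one; under neutrality it is (sub)uniform on
$[0,1]$, small when the sample is improbably even and near 1 when it is
improbably concentrated -- the signature of conformity or of a strong
age constraint on the copy pool.  The two-tailed decision at level
$\alpha$ rejects when either tail sum ($P_E$ or its upper counterpart,
both including ties) is at most $\alpha/2$; a one-tailed rule on $P_E$
alone would be blind to concentration excess entirely.  For small
$(n,k)$ the package enumerates all partitions; otherwise it estimates
the tail sums by Monte Carlo.

The conditional sampler needs no rejection step and no choice of
$\theta$: given $k$, the ESF configuration law equals the distribution
of cycle types of uniform random permutations of $n$ elements with
exactly $k$ cycles.  Such permutations are built by sequential
insertion, where element $t+1$ either opens a new cycle or joins the
cycle of a uniformly chosen earlier element, with exact transition
probabilities obtained from a completion-count table computed by a
Stirling-type recurrence.  The sampler is validated by chi-square
goodness of fit against enumerated exact probabilities.

Numerical choices: probabilities are compared in log space with relative
tolerance $10^{-9}$, ties counting as "no more probable" (so the test
is conservative at ties); Monte-Carlo p-values use add-one smoothing
$(\mathrm{count}+1)/(m+1)$ and default $m = 10^5$ draws.

## Diversity profiles and the classifier

Samples are summarized by Hill numbers
$^qD = (\sum_i p_i^q)^{1/(1-q)}$ on the grid
$q = 0, 0.25, \dots, 3$ (13 values), with the $q \to 1$ limit
$\exp(-\sum p_i \log p_i)$ substituted within $10^{-9}$ of $q = 1$.
Profiles use raw sample frequencies -- no small-sample bias correction
-- because the classifier is trained and applied on samples of the same
size, so any bias is common to both sides.

The generative-inference pipeline draws training parameters from
$b \sim N(0, 10^{-3})$ (an exact-zero point mass with probability 0.5
supplies the "unbiased" class; non-zero draws are resampled until
$|b| \ge 10^{-6}$ so the two classes are well separated),
$\mu \sim U(10^{-5}, 10^{-3})$, $p_{\mathrm{death}} \sim U(0.02, 0.1)$
and $c_{\mathrm{thresh}}$ discrete-uniform on $\{1, \dots, a_{\max}\}$
(the top value mapped to `"ALL"`), simulates each population to steady
state, samples at $n \in \{100, 500, 1000, 2000\}$, and trains one
random forest per sample size (500 trees, `mtry` $=\lfloor\sqrt{13}\rfloor = 3$,
bootstrap resampling, majority vote; a stratified 20% held-out split
records accuracy and feeds permutation importance).  The forest
hyper-parameters follow common random-forest defaults; the tree count
is large enough that vote fractions are stable to about $\pm 0.02$.

What the synthetic training data emulate -- and what they do not: the
generator produces exactly the model's stationary samples, so a
classifier trained on them answers "is this sample consistent with
unbiased transmission *under this model family*".  Real cultural data
add features the model lacks (variable population size, network and
spatial structure, time-averaged deposition, observation error), so
passing the package's tests shows fidelity to the model, not validity
of the model for any particular empirical system.

## Effective population size

`estimate_ne()` measures variance effective size on the generation
timescale of the *copying lineage*.  It tracks the frequency of one of
two neutral types in the reproductive core (individuals still young
enough to be copied; the whole population for `"ALL"`), because
individuals older than the pool limit are a passive archive whose
inertia suppresses short-lag variance without changing long-run drift.
Squared frequency changes are recorded over non-overlapping windows at
two lags, $L$ and $2L$ with $L = 5$ generations, and the
non-accumulating variance component (cohort sampling noise) is removed
exactly by differencing:
$\hat N_e = L \,/\, (T_{\mathrm{gen}} (\bar x_{2L} - \bar x_L))$, with
$x_L = (\Delta_L p)^2 / (p(1-p))$ and $T_{\mathrm{gen}}$ the mean age of
a role model at copying (`generation_time()`; $1/p_{\mathrm{death}}$ for
`"ALL"`, 1 for the '1' scenario).  Trajectories restart from a fresh
50/50 population when the frequency leaves $[0.1, 0.9]$; the standard
error is a bootstrap over replicate trajectories, and the relative
error scales like $\sqrt{2/\#\mathrm{windows}}$ (10000 windows,
about 2%, for the headline estimates).

The estimator reproduces every closed form available as an oracle:
$N$ in the Wright-Fisher limit, $N/2$ at $p_{\mathrm{death}} = 1/N$
(Moran), $N/(2 - p_{\mathrm{death}})$ for `"ALL"` (derivable from the
per-step binomial death/birth variance), and
$N p_{\mathrm{death}}$ for the '1' scenario (the newborn-cohort chain is
a Wright-Fisher chain of that size).

## Problem sizes used by the shipped experiments

The package's tests and the acceptance script use these scales, chosen
so each check retains clear statistical meaning: effective sizes at full
scale $N = 10^5$ (the cohort and frequency reductions make this cheap);
Ewens-Watterson rejection experiments at $N = 10^4$ with 100 populations
per condition and samples of $n \in \{1000, 2000\}$, using
$2 \times 10^4$ Monte-Carlo draws per p-value (tail-probability standard
error $\approx 0.0015$ near the decision threshold, ample for counting
rejections at $\alpha = 0.05$); modal sample
richness at full scale $N = 10^5$ with 2000 repeated samples; the
classifier pipeline at $N = 2000$, trained on 10,000 simulations under
the Wright-Fisher prior (the frequency-table engine makes these nearly
free) and 600 under the age-structured prior, with 40-250 evaluation
replicates per constellation.  The
qualitative properties checked at classifier desk scale (U-shaped
rejection in $b$, weak sample-size dependence on unbiased data, masking
of bias under strong age constraints) are scale-robust, but the absolute
rejection probabilities of the full-scale experiments (around 0.1 for
unbiased age-structured data) are not expected to be reproduced exactly
at reduced $N$.

## Known limitations

* The '1'-scenario effective size refers to the copying lineage's
  generation timescale; whole-population frequencies over wall-clock
  windows drift with a different (smaller) effective size because most
  of the population is a non-heritable archive.
* Monte-Carlo $P_E$ values are conservative near ties and never exactly
  zero by construction.
* The classifier refuses profiles whose sample size it was not trained
  for rather than interpolating.
* With $\mu$ at the low end of the training prior the populations are
  near-monomorphic and diversity profiles carry little signal; held-out
  accuracy well below 1 is expected and honest there.
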