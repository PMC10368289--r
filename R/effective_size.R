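# ---- cohort-level biallelic simulator ---------------------------------------

# Exact distributional reduction of the agent model for the neutral
# (mu = 0, b = 0) biallelic case used in effective-size estimation.
# Individuals within an age cohort are exchangeable, and with b = 0 the
# adoption probability is the pool frequency, so it suffices to track the
# per-age counts of the two types.  Ages above `cap` are pooled into the
# top bin (death is age-independent, and only ages <= c_thresh matter for
# the dynamics).
#
# State: integer vectors cntA, cntB of length cap + 1 (index a + 1 = age a).
init_biallelic_cohorts <- function(N, p_death, cap) {
  w <- p_death * (1 - p_death)^(0:cap)
  w[cap + 1L] <- (1 - p_death)^cap  # absorb the tail mass
  sizes <- as.integer(rmultinom(1L, N, w))
  # allocate floor(N/2) copies of type A across cohorts hypergeometrically
  nA <- N %/% 2L
  rem_slots <- N
  cntA <- integer(cap + 1L)
  for (a in seq_along(sizes)) {
    if (nA == 0L) break
    rem_slots <- rem_slots - sizes[a]
    cntA[a] <- rhyper(1L, sizes[a], rem_slots, nA)
    nA <- nA - cntA[a]
  }
  list(cntA = cntA, cntB = sizes - cntA)
}

# Advance the cohort state one step; returns the new state.
# c_thresh = "ALL" or a positive integer.
step_biallelic_cohorts <- function(state, N, p_death, c_thresh, cap) {
  cntA <- state$cntA
  cntB <- state$cntB
  # previous-snapshot ages 0..c_thresh-1 (= ages 1..c_thresh at copying)
  idx <- seq.int(1L, min(c_thresh, cap + 1L))
  poolA <- sum(cntA[idx])
  poolT <- poolA + sum(cntB[idx])
  if (poolT == 0L) {
    stop(sprintf(
      "empty copy pool: no individual with age (at copying) in [1, %d]",
      c_thresh), call. = FALSE)
  }
  deadA <- rbinom(length(cntA), cntA, p_death)
  deadB <- rbinom(length(cntB), cntB, p_death)
  n_dead <- sum(deadA) + sum(deadB)
  survA <- cntA - deadA
  survB <- cntB - deadB
  # survivors age by one; top bin absorbs
  newA <- c(0L, survA[seq_len(cap - 1L)], survA[cap] + survA[cap + 1L])
  newB <- c(0L, survB[seq_len(cap - 1L)], survB[cap] + survB[cap + 1L])
  bornA <- rbinom(1L, n_dead, poolA / poolT)
  newA[1L] <- bornA
  newB[1L] <- n_dead - bornA
  list(cntA = newA, cntB = newB)
}

# With an "ALL" pool ages are irrelevant (deaths are age-independent and
# the pool is the whole previous population), so the biallelic state
# collapses to the two type totals: O(1) per step.
step_biallelic_all <- function(nA, N, p_death) {
  deadA <- rbinom(1L, nA, p_death)
  deadB <- rbinom(1L, N - nA, p_death)
  bornA <- rbinom(1L, deadA + deadB, nA / N)
  nA - deadA + bornA
}

# ---- effective-size estimation ----------------------------------------------

#' Generation time of the copying lineage
#'
#' Mean age of a role model at the moment its copy is born -- the natural
#' generation time of the copying lineage.  Role models are uniform over
#' the copy pool, whose ages at copying follow the stationary geometric
#' profile truncated to `[1, c_thresh]` (untruncated for `"ALL"`).
#' `c_thresh = 1` gives exactly 1 (each newborn cohort copies the previous
#' one); `"ALL"` gives `1/p_death`; the Wright-Fisher limit `p_death = 1`
#' gives 1.
#'
#' @param p_death Per-step death probability.
#' @param c_thresh `"ALL"` or a positive integer.
#' @return Generation time in time steps.
#' @export
generation_time <- function(p_death, c_thresh = "ALL") {
  c_thresh <- canonical_c_thresh(c_thresh)
  if (is_all_pool(c_thresh)) return(1 / p_death)
  ages <- seq_len(c_thresh)
  w <- (1 - p_death)^(ages - 1L)
  sum(ages * w) / sum(w)
}

#' Variance effective population size of the age-structured model
#'
#' Estimates the variance effective size of the neutral age-structured
#' model from the drift of one of two selectively neutral variant types
#' (`mu = 0`, `b = 0`, 50/50 start).  The frequency `p_t` tracked is that
#' of the *reproductive core* -- individuals still young enough to be
#' copied (snapshot ages `0..c_thresh-1`; the whole population for
#' `"ALL"`) -- because older individuals are a passive archive of past
#' states whose inertia suppresses short-lag frequency variance without
#' affecting long-run drift.
#'
#' Neutral drift accumulates variance linearly in time,
#' `Var(p_{t+L} - p_t | p_t) = a + L p_t(1-p_t) / (Ne T_gen)`, where
#' `T_gen` is the lineage generation time ([generation_time()]) and the
#' intercept `a` collects non-accumulating fluctuation (cohort sampling
#' noise, finite-core effects).  The estimator therefore measures squared
#' frequency changes at two lags, `L` and `2L`, over non-overlapping
#' windows and removes the intercept by differencing:
#' `Ne = L / (T_gen * (mean(x_2L) - mean(x_L)))` with
#' `x_L = (dp_L)^2 / (p(1-p))`.  Trajectories restart from a fresh 50/50
#' population whenever the frequency leaves `band`; the standard error is
#' a bootstrap over replicate trajectories.
#'
#' In the Wright-Fisher limit (`p_death = 1`, `c_thresh = "ALL"`) the
#' estimator returns `N`; at `p_death = 1/N` it approaches the Moran value
#' `N/2` (see [moran_reference_ne()]); the '1' scenario gives
#' `N * p_death` and the 'ALL' scenario `N / (2 - p_death)`.
#'
#' @param N Population size.
#' @param p_death Per-step death probability.
#' @param c_thresh `"ALL"` or a positive integer (copy-pool age limit).
#' @param n_replicates Number of replicate trajectories.
#' @param min_windows Total number of lag-2L windows accumulated across
#'   replicates (controls precision).
#' @param horizon Maximum number of steps per replicate.
#' @param band Frequency band outside which a trajectory is restarted.
#' @param n_boot Bootstrap resamples for the standard error.
#' @param seed Optional integer seed.
#' @return An object of class `"ne_estimate"`: list with `ne`, `se`,
#'   `scenario`, `p_death`, `N`, `n_replicates`, `windows`.
#' @examples
#' \donttest{
#' estimate_ne(2000, p_death = 0.1, c_thresh = "ALL",
#'             min_windows = 500, seed = 1)
#' }
#' @export
estimate_ne <- function(N, p_death, c_thresh = "ALL", n_replicates = 24,
                        min_windows = 3000, horizon = NULL,
                        band = c(0.1, 0.9), n_boot = 200, seed = NULL) {
  c_thresh <- canonical_c_thresh(c_thresh)
  if (!is.null(seed)) set.seed(seed)
  t_gen <- generation_time(p_death, c_thresh)
  L <- ceiling(5 * t_gen)
  cap <- max(ceiling(20 / p_death), if (is_all_pool(c_thresh)) 1L
                                    else c_thresh + 1L)
  if (is.null(horizon)) horizon <- 400L * 2L * L
  windows_per_rep <- ceiling(min_windows / n_replicates)
  all_pool <- is_all_pool(c_thresh)
  core_idx <- if (all_pool) NULL else seq_len(min(c_thresh, cap + 1L))

  new_state <- function() {
    if (all_pool) N %/% 2L else init_biallelic_cohorts(N, p_death, cap)
  }
  freq <- function(s) {
    if (all_pool) return(s / N)
    coreA <- sum(s$cntA[core_idx])
    coreT <- coreA + sum(s$cntB[core_idx])
    if (coreT == 0L) return(NA_real_)
    coreA / coreT
  }
  advance <- function(s, len) {
    if (all_pool) {
      for (i in seq_len(len)) s <- step_biallelic_all(s, N, p_death)
    } else {
      for (i in seq_len(len)) {
        s <- step_biallelic_cohorts(s, N, p_death, c_thresh, cap)
      }
    }
    s
  }

  # per replicate: sums and counts of x_L (half-windows) and x_2L
  rep_sums <- matrix(0, n_replicates, 4,
                     dimnames = list(NULL, c("xL", "nL", "x2L", "n2L")))
  rep_windows <- integer(n_replicates)
  for (r in seq_len(n_replicates)) {
    state <- new_state()
    steps <- 0L
    while (rep_windows[r] < windows_per_rep && steps < horizon) {
      p0 <- freq(state)
      if (is.na(p0) || p0 < band[1] || p0 > band[2]) {
        state <- new_state()
        p0 <- freq(state)
      }
      state <- advance(state, L)
      pm <- freq(state)
      state <- advance(state, L)
      p1 <- freq(state)
      steps <- steps + 2L * L
      if (is.na(pm) || is.na(p1)) next
      add <- c((pm - p0)^2 / (p0 * (1 - p0)), 1, (p1 - p0)^2 /
               (p0 * (1 - p0)), 1)
      if (pm > band[1] && pm < band[2]) {
        add[1:2] <- add[1:2] + c((p1 - pm)^2 / (pm * (1 - pm)), 1)
      }
      rep_sums[r, ] <- rep_sums[r, ] + add
      rep_windows[r] <- rep_windows[r] + 1L
    }
  }
  if (sum(rep_windows) == 0L) {
    stop("no usable drift windows; increase N or the horizon",
         call. = FALSE)
  }
  ratio <- function(sums) {
    s <- colSums(sums)
    L / (t_gen * (s["x2L"] / s["n2L"] - s["xL"] / s["nL"]))
  }
  ne <- unname(ratio(rep_sums))
  boot <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n_replicates, replace = TRUE)
    ratio(rep_sums[idx, , drop = FALSE])
  }, numeric(1))
  structure(
    list(ne = ne, se = sd(boot),
         scenario = if (all_pool) "ALL" else as.character(c_thresh),
         p_death = p_death, N = N, n_replicates = n_replicates,
         windows = sum(rep_windows)),
    class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf(
    "Variance effective size: Ne = %.0f (SE %.0f)\n", x$ne, x$se))
  cat(sprintf("  N = %d, p_death = %g, c_thresh = %s, %d windows\n",
              x$N, x$p_death, x$scenario, x$windows))
  invisible(x)
}

#' Moran-model reference effective size
#'
#' The effective size of the Moran model, `N / 2` -- the limit of the
#' age-structured 'ALL' scenario as `p_death` approaches `1/N` (one birth
#' and one death per step).
#'
#' @param N Population size, `N >= 2`.
#' @return `N / 2`.
#' @export
moran_reference_ne <- function(N) {
  if (N < 2) stop("`N` must be >= 2", call. = FALSE)
  N / 2
}
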