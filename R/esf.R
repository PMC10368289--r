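#' Ewens sampling formula log-probability of a configuration
#'
#' Under neutrality, conditional on sample size `n` and number of types
#' `k`, the probability of an *ordered* type-count tuple
#' `(n_1, ..., n_k)` is
#' `P(n_1, ..., n_k | n, k) = n! / (|S_n^k| k! n_1 ... n_k)`,
#' with `|S_n^k|` the unsigned Stirling number of the first kind.  The
#' probability of the corresponding *unordered* multiset multiplies this by
#' the number of distinct orderings `k! / prod_j m_j!` (`m_j` =
#' multiplicity of the count value `j`).  The Ewens-Watterson test statistic
#' uses the ordered form consistently; the unordered form is the actual
#' sampling distribution of configurations.
#'
#' @param config A [sample_configuration()] (or positive counts).
#' @param ordered If `TRUE` (default) return the ordered-tuple
#'   log-probability; otherwise the unordered multiset log-probability.
#' @return The natural log-probability.
#' @examples
#' exp(esf_log_prob(sample_configuration(2)))          # n = 2, k = 1: 1
#' exp(esf_log_prob(sample_configuration(c(2, 1))))    # 1/2
#' @export
esf_log_prob <- function(config, ordered = TRUE) {
  config <- sample_configuration(config)
  n <- config_n(config)
  k <- config_k(config)
  counts <- as.integer(config)
  lp <- lfactorial(n) - log_stirling1(n, k) - lfactorial(k) -
    sum(log(counts))
  if (!ordered) {
    mult <- table(counts)
    lp <- lp + lfactorial(k) - sum(lfactorial(as.integer(mult)))
  }
  lp
}

#' Enumerate all configurations with n observations and k types
#'
#' Lists every partition of `n` into exactly `k` positive parts in
#' canonical (non-increasing) form -- the support of the Ewens sampling
#' formula conditional on `(n, k)`.
#'
#' @param n Sample size.
#' @param k Number of types, `1 <= k <= n`.
#' @param max_configs Enumeration guard: error if the partition count
#'   `p(n, k)` exceeds this (direct the caller to the Monte-Carlo path).
#' @return A list of [sample_configuration()] objects.
#' @examples
#' enumerate_configs(4, 2)  # (3,1) and (2,2)
#' @export
enumerate_configs <- function(n, k, max_configs = 2e5) {
  if (k < 1 || k > n) stop("require 1 <= k <= n", call. = FALSE)
  n_parts <- count_partitions(n, k)
  if (n_parts > max_configs) {
    stop(sprintf(
      "p(%d, %d) = %g partitions exceeds max_configs = %g; use the Monte-Carlo path",
      n, k, n_parts, max_configs), call. = FALSE)
  }
  out <- vector("list", n_parts)
  idx <- 0L
  parts <- integer(k)
  # non-increasing parts, part i at most `cap` and at least ceil(rem / slots)
  recurse <- function(pos, rem, cap) {
    slots <- k - pos + 1L
    if (pos > k) {
      if (rem == 0L) {
        idx <<- idx + 1L
        out[[idx]] <<- sample_configuration(parts)
      }
      return(invisible(NULL))
    }
    hi <- min(cap, rem - (slots - 1L))
    lo <- ceiling(rem / slots)
    if (hi < lo) return(invisible(NULL))
    for (v in seq.int(hi, lo)) {
      parts[pos] <<- v
      recurse(pos + 1L, rem - v, v)
    }
    invisible(NULL)
  }
  recurse(1L, n, n)
  out[seq_len(idx)]
}

#' Sample configurations from the ESF conditioned on the number of types
#'
#' Draws configurations distributed according to the Ewens sampling
#' formula conditional on `(n, k)`.  The conditional law given `k` does not
#' depend on the mutation parameter theta (k is sufficient for theta), and
#' equals the distribution of cycle types of uniform random permutations of
#' `n` elements with exactly `k` cycles.  Such permutations are sampled
#' directly by sequential insertion with exact transition probabilities
#' from a Stirling-style completion table, so no rejection step is needed.
#'
#' @param n Sample size.
#' @param k Number of types.
#' @param draws Number of configurations to draw.
#' @param seed Optional integer seed (set once before drawing).
#' @return A list of `draws` [sample_configuration()] objects.
#' @examples
#' sample_config_given_k(5, 2, draws = 3, seed = 1)
#' @export
sample_config_given_k <- function(n, k, draws = 1, seed = NULL) {
  if (k < 1 || k > n) stop("require 1 <= k <= n", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  res <- sample_configs_ck_cpp(n, k, new_cycle_probs(n, k),
                               as.integer(draws), TRUE)
  lapply(res$configs, sample_configuration)
}

#' Expected number of types in an ESF sample
#'
#' The Ewens expectation `E[K] = sum_{i=0}^{n-1} theta / (theta + i)` for a
#' sample of size `n` at scaled innovation rate `theta = 2 N_e mu`.
#'
#' @param theta Scaled innovation rate.
#' @param n Sample size.
#' @return Expected richness.
#' @export
ewens_expected_richness <- function(theta, n) {
  sum(theta / (theta + seq.int(0L, n - 1L)))
}
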