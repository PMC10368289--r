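#' Ewens-Watterson (Slatkin exact) test of neutrality
#'
#' Two-tailed exact test of whether an observed variant-abundance
#' configuration is consistent with a sample from a neutrally evolving
#' (Wright-Fisher, infinite-alleles) population.  Conditional on the sample
#' size `n` and number of types `k`, the tail probability is
#' `P_E = sum over configurations with P(n_j | n, k) <= P(n_0)` of their
#' probability, where `P` is the Ewens sampling formula.  Under neutrality
#' `P_E` is (sub)uniform on `[0, 1]`: values near 0 mean the configuration
#' is improbably *even*, values near 1 improbably *concentrated* (the
#' signature of conformity or of a strong age constraint).  The two-tailed
#' decision at level `alpha` therefore rejects when either tail sum --
#' `P_E` or its upper-tail counterpart
#' `sum over P(n_j | n, k) >= P(n_0)` -- is at most `alpha / 2`; both sums
#' include the tied configurations, so monomorphic samples (`k = 1`, a
#' single possible configuration) are never rejected.
#'
#' When the partition count `p(n, k)` is small enough the tail sums are
#' computed exhaustively; otherwise they are estimated by Monte Carlo from
#' configurations sampled exactly from the conditional ESF (see
#' [sample_config_given_k()]), with add-one smoothing
#' `(count + 1) / (mc_samples + 1)` so estimated tail probabilities are
#' never zero.  Probabilities are compared in log space with relative
#' tolerance `1e-9`, ties counting into both tails.
#'
#' @param observed A [sample_configuration()] (or positive counts).
#' @param mc_samples Monte-Carlo draws used when enumeration is
#'   intractable (default `1e5`).
#' @param exact_limit Use exhaustive enumeration when the number of
#'   partitions `p(n, k)` is at most this.
#' @param alpha Significance level used for the `reject` field.
#' @param seed Optional integer seed for the Monte-Carlo path.
#' @return An object of classes `"ewens_test"` and `"htest"`, with
#'   `p.value` (`P_E`, the lower-tail sum), `p.upper` (the upper-tail
#'   sum), `reject` (the two-tailed decision at `alpha`), `parameter`
#'   (`n`, `k`, `mc_samples`; `mc_samples` is 0 for the exhaustive path)
#'   and `method`.
#' @examples
#' ewens_watterson_test(sample_configuration(c(5, 1, 1, 1)))
#' @export
ewens_watterson_test <- function(observed, mc_samples = 1e5,
                                 exact_limit = 1e5, alpha = 0.05,
                                 seed = NULL) {
  observed <- sample_configuration(observed)
  n <- config_n(observed)
  k <- config_k(observed)
  lp_obs <- esf_log_prob(observed, ordered = TRUE)
  tol <- 1e-9 * max(1, abs(lp_obs))

  if (k == 1L || k == n) {
    # single possible configuration
    p_value <- 1
    p_upper <- 1
    method <- "exhaustive"
    mc_used <- 0L
  } else if (count_partitions(n, k) <= exact_limit) {
    configs <- enumerate_configs(n, k, max_configs = exact_limit)
    lp_ord <- vapply(configs, esf_log_prob, numeric(1), ordered = TRUE)
    lp_unord <- vapply(configs, esf_log_prob, numeric(1), ordered = FALSE)
    p_value <- min(1, sum(exp(lp_unord[lp_ord <= lp_obs + tol])))
    p_upper <- min(1, sum(exp(lp_unord[lp_ord >= lp_obs - tol])))
    method <- "exhaustive"
    mc_used <- 0L
  } else {
    if (mc_samples < 1000) {
      warning("mc_samples < 1000: Monte-Carlo p-value will be coarse")
    }
    if (!is.null(seed)) set.seed(seed)
    res <- sample_configs_ck_cpp(n, k, new_cycle_probs(n, k),
                                 as.integer(mc_samples), FALSE)
    # lp_ord(draw) <= lp_obs  <=>  sum(log n_i) >= sum(log n_obs,i)
    sumlog_obs <- sum(log(as.integer(observed)))
    p_value <- (sum(res$sumlog >= sumlog_obs - tol) + 1) /
      (mc_samples + 1)
    p_upper <- (sum(res$sumlog <= sumlog_obs + tol) + 1) /
      (mc_samples + 1)
    method <- "monte_carlo"
    mc_used <- as.integer(mc_samples)
  }

  structure(
    list(
      statistic = c("log P(n0 | n, k)" = lp_obs),
      parameter = c(n = n, k = k, mc_samples = mc_used),
      p.value = p_value,
      p.upper = p_upper,
      reject = p_value <= alpha / 2 || p_upper <= alpha / 2,
      alpha = alpha,
      method = sprintf("Ewens-Watterson exact test of neutrality (%s)",
                       method),
      data.name = sprintf("configuration with n = %d, k = %d", n, k),
      mc_method = method
    ),
    class = c("ewens_test", "htest")
  )
}
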