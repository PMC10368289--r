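test_that("Stirling numbers of the first kind satisfy known identities", {
  expect_equal(log_stirling1(7, 7), 0)
  expect_equal(exp(log_stirling1(4, 2)), 11)
  expect_equal(exp(log_stirling1(5, 2)), 50)
  for (n in c(3, 6, 10)) {
    expect_equal(log_stirling1(n, 1), lfactorial(n - 1))
  }
  expect_error(log_stirling1(3, 4), "<=")
  expect_error(log_stirling1(3, 0), "<=")
})

test_that("ESF probabilities match hand computations and normalize", {
  expect_equal(exp(esf_log_prob(c(2))), 1)
  expect_equal(exp(esf_log_prob(c(2, 1))), 0.5)
  # ordered and unordered forms differ by the multiplicity factor
  expect_equal(esf_log_prob(c(3, 1), ordered = FALSE),
               esf_log_prob(c(3, 1), ordered = TRUE) + log(2))
  for (n in 2:8) {
    for (k in 1:n) {
      total <- sum(exp(vapply(enumerate_configs(n, k), esf_log_prob,
                              numeric(1), ordered = FALSE)))
      expect_equal(total, 1, tolerance = 1e-12)
    }
  }
})

test_that("partition enumeration is complete and guarded", {
  e42 <- enumerate_configs(4, 2)
  expect_identical(lapply(e42, as.integer),
                   list(c(3L, 1L), c(2L, 2L)))
  expect_identical(as.integer(enumerate_configs(5, 5)[[1]]),
                   rep(1L, 5))
  expect_length(enumerate_configs(10, 3), 8L)
  expect_error(enumerate_configs(200, 30, max_configs = 100),
               "Monte-Carlo")
})

test_that("the conditioned sampler reproduces the conditional ESF law", {
  expect_identical(as.integer(sample_config_given_k(6, 6, 1,
                                                    seed = 1)[[1]]),
                   rep(1L, 6))
  expect_identical(as.integer(sample_config_given_k(100, 1, 1,
                                                    seed = 1)[[1]]),
                   100L)
  set.seed(20)
  for (nk in list(c(6, 2), c(8, 3), c(10, 4))) {
    n <- nk[1]; k <- nk[2]
    configs <- enumerate_configs(n, k)
    keys <- vapply(configs, function(cf) paste(cf, collapse = ","), "")
    probs <- exp(vapply(configs, esf_log_prob, numeric(1),
                        ordered = FALSE))
    draws <- sample_config_given_k(n, k, draws = 4000)
    got <- factor(vapply(draws, function(cf) paste(cf, collapse = ","),
                         ""), levels = keys)
    # collapse cells with tiny expectation to keep chi-square valid
    counts <- as.vector(table(got))
    keep <- probs * 4000 >= 5
    chi <- if (any(!keep)) {
      chisq.test(c(counts[keep], sum(counts[!keep])),
                 p = c(probs[keep], sum(probs[!keep])),
                 rescale.p = TRUE)
    } else {
      chisq.test(counts, p = probs, rescale.p = TRUE)
    }
    expect_gt(chi$p.value, 0.01)
  }
})

test_that("the neutrality test is exact, stable and permutation-invariant", {
  # single-configuration cases
  expect_equal(ewens_watterson_test(c(7))$p.value, 1)
  expect_equal(ewens_watterson_test(rep(1, 9))$p.value, 1)
  # canonicalization: count order cannot matter
  expect_equal(ewens_watterson_test(c(3, 1, 2))$p.value,
               ewens_watterson_test(c(1, 2, 3))$p.value)
  # Monte-Carlo path agrees with exhaustive enumeration
  cfg <- sample_configuration(c(8, 4, 2, 1, 1))
  ex <- ewens_watterson_test(cfg)
  expect_identical(ex$mc_method, "exhaustive")
  mc <- ewens_watterson_test(cfg, exact_limit = 0, mc_samples = 2e5,
                             seed = 3)
  expect_identical(ex$mc_method, "exhaustive")
  expect_lt(abs(ex$p.value - mc$p.value), 0.01)
  # p-values are probabilities
  expect_gte(mc$p.value, 0)
  expect_lte(ex$p.value, 1)
})

test_that("rejection power grows with frequency-dependence strength", {
  # scaled-down power check: neutral WF populations are rarely rejected,
  # strong conformity (concentration excess, upper tail) essentially
  # always, mild anti-conformity (evenness excess, lower tail) at an
  # intermediate rate (N = 1e4, n = 2000, 20 populations each)
  grid <- data.frame(b = c(0, 5e-3, -1e-3), p_death = 1,
                     c_thresh = "ALL")
  res <- rejection_experiment(grid, n_reps = 20, sample_sizes = 2000,
                              method = "ewens", N = 1e4, mu = 5e-4,
                              alpha = 0.05, mc_samples = 2e4, seed = 601)
  expect_gt(res$rejections[2], res$rejections[1])
  expect_gt(res$rejections[3], res$rejections[1])
})
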