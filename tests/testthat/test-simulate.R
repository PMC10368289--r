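test_that("neutral drift absorbs and fixes at the initial frequency", {
  set.seed(10)
  # mu = 0 from 50/50: exactly one type survives
  tab <- run_wright_fisher(100, mu = 0, init_counts = c(50, 50),
                           generations = 1e6, stop_at_fixation = TRUE)
  expect_length(tab$labels, 1L)
  expect_identical(tab$counts, 100L)

  # martingale: fixation probability of the majority type = 0.6
  fixed_major <- replicate(3000, {
    t <- run_wright_fisher(100, mu = 0, init_counts = c(60, 40),
                           generations = 1e6, stop_at_fixation = TRUE)
    t$labels == 0L
  })
  se <- sqrt(0.6 * 0.4 / 3000)
  expect_lt(abs(mean(fixed_major) - 0.6), 3 * se)
})

test_that("steady-state sample richness matches the Ewens expectation", {
  set.seed(11)
  N <- 2000; mu <- 5e-3; n <- 500
  theta <- 2 * N * mu
  expected <- ewens_expected_richness(theta, n)
  ks <- replicate(20, {
    tab <- run_wright_fisher(N, mu)
    attr(sample_variants(tab, n), "k")
  })
  expect_lt(abs(mean(ks) - expected), 3 * sd(ks) / sqrt(20))
})

test_that("agent engine and frequency engine agree at p_death = 1", {
  set.seed(12)
  N <- 500; mu <- 5e-3
  params <- sim_params(N, mu, p_death = 1, c_thresh = "ALL")
  reps <- 50
  stats_freq <- replicate(reps, {
    tab <- run_to_steady_state(params, engine = "freq")$table
    c(k = length(tab$labels), het = heterozygosity(tab))
  })
  stats_agent <- replicate(reps, {
    tab <- run_to_steady_state(params, engine = "agent")$table
    c(k = length(tab$labels), het = heterozygosity(tab))
  })
  expect_gt(ks.test(stats_freq["k", ], stats_agent["k", ])$p.value, 0.01)
  expect_gt(ks.test(stats_freq["het", ], stats_agent["het", ])$p.value,
            0.01)
})

test_that("age-constrained richness drops as p_death decreases", {
  # fewer newborns and a smaller copy pool mean stronger drift: the '1'
  # scenario holds fewer variant types at low p_death (paired seeds)
  k_at <- function(p_death, seed) {
    params <- sim_params(2000, mu = 2e-3, p_death = p_death, c_thresh = 1)
    length(run_to_steady_state(params, seed = seed)$table$labels)
  }
  seeds <- 101:130
  k_low <- vapply(seeds, function(s) k_at(0.02, s), numeric(1))
  k_high <- vapply(seeds, function(s) k_at(0.1, s + 1000), numeric(1))
  expect_lt(mean(k_low), mean(k_high))
})

test_that("steady-state runs converge and are reproducible", {
  params <- sim_params(300, mu = 1e-3, p_death = 0.1, c_thresh = 2)
  ss1 <- run_to_steady_state(params, seed = 42)
  ss2 <- run_to_steady_state(params, seed = 42)
  expect_true(ss1$converged)
  expect_identical(ss1$table$counts, ss2$table$counts)
  expect_identical(ss1$population$variants, ss2$population$variants)

  # mu = 0 monomorphic start: richness trajectory constant at 1
  ss0 <- run_to_steady_state(sim_params(200, mu = 0, p_death = 0.5),
                             seed = 1, generations = 300)
  expect_true(ss0$converged)
  expect_true(all(ss0$richness$richness == 1L))
})
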