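test_that("generation time interpolates between the known limits", {
  expect_equal(generation_time(1, "ALL"), 1)
  expect_equal(generation_time(0.02, "ALL"), 50)
  expect_equal(generation_time(0.5, 1), 1)
  expect_equal(generation_time(0.02, 1), 1)
  # pool spanning ages 1..c: mean age weighted by survivorship
  expect_equal(generation_time(0.5, 2), (1 + 2 * 0.5) / 1.5)
  expect_gt(generation_time(0.02, 20), generation_time(0.02, 5))
})

test_that("moran reference size is N / 2", {
  expect_equal(moran_reference_ne(1e5), 5e4)
  expect_equal(moran_reference_ne(2), 1)
  expect_error(moran_reference_ne(1), "N")
})

test_that("the cohort reduction matches the agent model distributionally", {
  # neutral biallelic '1' scenario at small N: whole-population frequency
  # after a fixed horizon, agent engine vs cohort-count engine
  set.seed(40)
  N <- 400; p_death <- 0.2; steps <- 120
  freq_agent <- replicate(80, {
    pop <- init_population(sim_params(N, 0, p_death, c_thresh = 1))
    pop$variants <- as.integer(runif(N) < 0.5)
    pop$next_label <- 2L
    out <- run_agent(pop, sim_params(N, 0, p_death, c_thresh = 1), steps)
    mean(out$population$variants == 1L)
  })
  cap <- ceiling(20 / p_death)
  freq_cohort <- replicate(80, {
    st <- agedrift:::init_biallelic_cohorts(N, p_death, cap)
    for (i in seq_len(steps)) {
      st <- agedrift:::step_biallelic_cohorts(st, N, p_death, 1L, cap)
    }
    sum(st$cntA) / N
  })
  expect_gt(ks.test(freq_agent, freq_cohort)$p.value, 0.01)
})

test_that("variance Ne recovers the Wright-Fisher and Moran limits", {
  e_wf <- estimate_ne(1000, p_death = 1, c_thresh = "ALL",
                      min_windows = 2000, seed = 41)
  expect_equal(e_wf$ne, 1000, tolerance = 0.1)
  expect_gt(e_wf$se, 0)

  e_moran <- estimate_ne(200, p_death = 1 / 200, c_thresh = "ALL",
                         min_windows = 1200, seed = 42)
  expect_equal(e_moran$ne, moran_reference_ne(200), tolerance = 0.12)
})

test_that("scenario effective sizes follow the age-structure laws", {
  # 'ALL': Ne = N / (2 - p_death); '1': Ne = N * p_death; monotone in
  # p_death in both scenarios
  e_all <- estimate_ne(5000, p_death = 0.1, c_thresh = "ALL",
                       min_windows = 2000, seed = 43)
  expect_equal(e_all$ne, 5000 / 1.9, tolerance = 0.1)

  e_one_a <- estimate_ne(5000, p_death = 0.05, c_thresh = 1,
                         min_windows = 1500, seed = 44)
  e_one_b <- estimate_ne(5000, p_death = 0.1, c_thresh = 1,
                         min_windows = 1500, seed = 45)
  expect_equal(e_one_a$ne, 250, tolerance = 0.1)
  expect_equal(e_one_b$ne, 500, tolerance = 0.1)
  expect_lt(e_one_a$ne, e_one_b$ne)
})
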