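test_that("initial population is monomorphic with stationary ages", {
  set.seed(1)
  pop <- init_population(sim_params(N = 5, mu = 0.1, p_death = 0.3))
  expect_length(pop$ages, 5L)
  expect_true(all(pop$variants == 0L))
  expect_identical(pop$next_label, 1L)

  # p_death = 1: geometric age law degenerates at 0
  pop1 <- init_population(sim_params(N = 100, mu = 0, p_death = 1))
  expect_true(all(pop1$ages == 0L))

  # geometric mean age (1 - p) / p
  set.seed(2)
  popg <- init_population(sim_params(N = 1e5, mu = 0, p_death = 0.02))
  expect_equal(mean(popg$ages), 49, tolerance = 0.05)
})

test_that("copy pool respects the age window and errors when empty", {
  pop <- make_pop(c(3, 2), ages = c(0L, 7L, 7L, 0L, 7L))
  expect_identical(copy_pool(pop, "ALL")$total, 5L)
  # ages at copying are snapshot ages + 1: the age-0 pair is the c=1 pool
  p1 <- copy_pool(pop, 1)
  expect_identical(p1$total, 2L)
  expect_identical(p1$labels, c(0L, 1L))
  # youngest snapshot member of the rest is 7 (age 8 at copying) > 5
  pop_old <- make_pop(c(4), ages = 7L)
  expect_error(copy_pool(pop_old, 5), "empty copy pool")
})

test_that("adoption probabilities follow the frequency-dependent rule", {
  pool <- copy_pool(make_pop(c(60, 40)), "ALL")
  d0 <- adoption_distribution(pool, b = 0, mu = 0)
  expect_equal(d0$probs, c(0.6, 0.4))
  d1 <- adoption_distribution(pool, b = 1, mu = 0)
  expect_equal(d1$probs, c(9 / 13, 4 / 13))
  dm <- adoption_distribution(pool, b = 0, mu = 0.1)
  expect_equal(sum(dm$probs), 0.9)
  expect_equal(dm$innovation_mass, 0.1)
  expect_error(adoption_distribution(pool, b = -1, mu = 0), "b")
})

test_that("b = 0 reduces the biased rule to linear copying exactly", {
  set.seed(3)
  for (i in 1:20) {
    counts <- sample.int(50, sample(2:8, 1))
    pool <- copy_pool(make_pop(counts), "ALL")
    mu <- runif(1, 0, 0.5)
    lin <- pool$counts / pool$total * (1 - mu)
    expect_equal(adoption_distribution(pool, b = 0, mu = mu)$probs, lin,
                 tolerance = 1e-15)
  }
})

test_that("stepping conserves size, freshens labels, uses the prev pool", {
  set.seed(4)
  params <- sim_params(N = 200, mu = 0.2, p_death = 0.3)
  pop <- init_population(params)
  for (i in 1:20) {
    nxt <- step_population(pop, params)
    expect_length(nxt$variants, 200L)
    expect_true(all(nxt$variants < nxt$next_label))
    expect_gte(nxt$next_label, pop$next_label)
    # newborn variants come from the previous population or are new
    born <- nxt$ages == 0L
    old_label <- nxt$variants[born] < pop$next_label
    expect_true(all(nxt$variants[born][old_label] %in% pop$variants))
    pop <- nxt
  }
})

test_that("no deaths means pure aging; mu = 0 monomorphy is absorbing", {
  set.seed(5)
  params <- sim_params(N = 50, mu = 0.5, p_death = 1e-12, max_age = 100)
  pop <- make_pop(rep(1, 50), ages = sample(0:20, 50, replace = TRUE))
  nxt <- step_population(pop, params)
  expect_identical(nxt$ages, pop$ages + 1L)
  expect_identical(nxt$variants, pop$variants)

  params0 <- sim_params(N = 50, mu = 0, p_death = 0.5)
  pop <- init_population(params0)
  for (i in 1:10) pop <- step_population(pop, params0)
  expect_identical(unique(pop$variants), 0L)
})

test_that("realized deaths match N * p_death on average", {
  set.seed(6)
  params <- sim_params(N = 2e4, mu = 0, p_death = 0.02)
  pop <- init_population(params)
  born <- replicate(300, {
    pop <<- step_population(pop, params)
    sum(pop$ages == 0L)
  })
  se <- sqrt(params$N * 0.02 * 0.98 / 300)
  expect_lt(abs(mean(born) - params$N * params$p_death), 3 * se)
})

test_that("sampling without replacement is hypergeometric", {
  pop <- make_pop(c(50, 50))
  expect_error(sample_variants(pop, 101), "n")
  full <- sample_variants(pop, 100)
  expect_identical(as.integer(full), c(50L, 50L))
  mono <- sample_variants(make_pop(30), 12)
  expect_identical(as.integer(mono), 12L)
  expect_identical(attr(mono, "k"), 1L)

  set.seed(7)
  counts <- replicate(5000, max(sample_variants(pop, 10)))
  # count of the majority type among 10 draws: mean of max(X, 10 - X),
  # X ~ Hypergeometric(50, 50, 10); compare against exact expectation
  x <- 0:10
  px <- dhyper(x, 50, 50, 10)
  exp_max <- sum(pmax(x, 10 - x) * px)
  se <- sqrt(sum((pmax(x, 10 - x) - exp_max)^2 * px) / 5000)
  expect_lt(abs(mean(counts) - exp_max), 3 * se)
})
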