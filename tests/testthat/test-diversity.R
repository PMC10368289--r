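test_that("Hill numbers hit closed-form values", {
  expect_equal(hill_number(rep(0.25, 4), c(0, 0.5, 1, 2, 3)),
               rep(4, 5))
  expect_equal(hill_number(1, c(0, 1, 2)), rep(1, 3))
  expect_equal(hill_number(c(0.5, 0.25, 0.25), 2), 1 / 0.375)
  p <- c(0.6, 0.3, 0.1)
  expect_equal(hill_number(p, 1), exp(-sum(p * log(p))))
  expect_error(hill_number(c(0.5, 0.4), 1), "sum to 1")
  expect_error(hill_number(c(1.2, -0.2), 1), "positive")
  expect_error(hill_number(c(0.5, 0.5), -1), "q")
})

test_that("profiles are monotone in q and continuous at q = 1", {
  set.seed(30)
  for (i in 1:25) {
    p <- as.vector(rmultinom(1, 500, runif(sample(2:12, 1))))
    p <- p[p > 0] / sum(p)
    qs <- seq(0, 3, by = 0.1)
    vals <- hill_number(p, qs)
    expect_true(all(diff(vals) <= 1e-10))
    expect_lt(abs(hill_number(p, 1 + 1e-6) - exp(-sum(p * log(p)))),
              1e-4)
    expect_lt(abs(hill_number(p, 1 - 1e-6) - exp(-sum(p * log(p)))),
              1e-4)
  }
})

test_that("diversity profiles have the documented feature layout", {
  prof <- diversity_profile(sample_configuration(c(10, 10, 10, 10)))
  expect_length(prof, 13L)
  expect_equal(attr(prof, "q_grid"), seq(0, 3, by = 0.25))
  expect_true(all(abs(prof - 4) < 1e-12))
  expect_identical(attr(prof, "n"), 40L)

  flat <- diversity_profile(sample_configuration(25))
  expect_true(all(abs(flat - 1) < 1e-12))

  # q = 0 entry is exactly the integer richness; scaling every count
  # leaves relative frequencies, hence the whole profile, unchanged
  set.seed(31)
  for (i in 1:50) {
    counts <- sample.int(40, sample(1:10, 1), replace = TRUE)
    prof <- diversity_profile(sample_configuration(counts))
    expect_identical(prof[[1]], as.numeric(length(counts)))
    scaled <- diversity_profile(sample_configuration(counts * 3L))
    expect_equal(as.numeric(scaled), as.numeric(prof))
  }
})
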