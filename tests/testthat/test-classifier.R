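# Synthetic, linearly separable training frame: label decided by q0.
synthetic_training <- function(n_rows, sample_size = 100L, seed = 1) {
  set.seed(seed)
  fn <- agedrift:::feature_names()
  feats <- matrix(runif(n_rows * 13, 1, 50), n_rows, 13,
                  dimnames = list(NULL, fn))
  df <- as.data.frame(feats, check.names = FALSE)
  df$label <- ifelse(df$q0 > 25, "biased", "unbiased")
  df$sample_size <- sample_size
  df
}

test_that("prior draws respect the stated parameter laws", {
  set.seed(50)
  prior <- prior_spec()
  draws <- replicate(4000, {
    d <- draw_training_params(prior, N = 1000)
    c(b = d$params$b, mu = d$params$mu, p_death = d$params$p_death,
      unbiased = d$label == "unbiased")
  })
  expect_true(all(draws["mu", ] >= 1e-5 & draws["mu", ] <= 1e-3))
  expect_true(all(draws["p_death", ] >= 0.02 & draws["p_death", ] <= 0.1))
  frac <- mean(draws["unbiased", ])
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 4000))
  expect_true(all(draws["b", draws["unbiased", ] == 1] == 0))
  biased_b <- draws["b", draws["unbiased", ] == 0]
  expect_true(all(abs(biased_b) >= prior$b_min))

  all_unbiased <- prior_spec(unbiased_fraction = 1)
  expect_true(all(replicate(50,
    draw_training_params(all_unbiased, 1000)$label) == "unbiased"))
})

test_that("forests learn a separable rule and vote consistently", {
  df <- synthetic_training(400)
  bundle <- train_classifier(df, num_trees = 200, seed = 2)
  expect_gt(bundle$heldout_accuracy["100"], 0.95)

  # prediction equals the majority of per-tree votes
  held <- bundle$heldout[["100"]]
  fit <- bundle$forests[["100"]]
  fn <- bundle$feature_names
  votes <- predict(fit, data = held[fn], predict.all = TRUE)$predictions
  bidx <- which(fit$forest$levels == "biased")
  vf <- rowMeans(votes == bidx)
  majority <- ifelse(vf > 0.5, "biased", "unbiased")
  plain <- as.character(predict(fit, data = held[fn])$predictions)
  expect_identical(majority[vf != 0.5], plain[vf != 0.5])

  # single-tree bundle still classifies
  b1 <- train_classifier(df, num_trees = 1, seed = 3)
  prof <- structure(as.numeric(df[1, fn]), q_grid = default_q_grid(),
                    n = 100L, class = "diversity_profile")
  res <- classify_profile(b1, prof)
  expect_true(res$label %in% c("biased", "unbiased"))
  expect_true(res$vote_fraction >= 0 && res$vote_fraction <= 1)

  # unknown sample size is refused with the available sizes named
  attr(prof, "n") <- 999L
  expect_error(classify_profile(bundle, prof), "available: 100")

  expect_error(train_classifier(df[df$label == "biased", ]),
               "both labels")
})

test_that("permutation importance flags informative features only", {
  df <- synthetic_training(500, seed = 4)
  # make all features except q0 pure noise already (they are); importance
  # must concentrate on q0
  bundle <- train_classifier(df, num_trees = 200, seed = 5)
  imp <- permutation_importance(bundle, n_permutations = 10, seed = 6)
  expect_identical(nrow(imp), 13L)
  imp_q0 <- imp$importance[imp$q == 0]
  expect_gt(imp_q0, 0.2)
  expect_true(all(abs(imp$importance[imp$q != 0]) < 0.05))

  # shuffling everything drops accuracy to the majority-class baseline
  held <- bundle$heldout[["100"]]
  fit <- bundle$forests[["100"]]
  fn <- bundle$feature_names
  set.seed(7)
  shuffled <- as.data.frame(lapply(held[fn], sample),
                            check.names = FALSE)
  names(shuffled) <- fn
  acc <- mean(predict(fit, data = shuffled)$predictions == held$label)
  baseline <- max(table(held$label)) / nrow(held)
  expect_lt(acc, baseline + 0.12)
})

test_that("training sets and classifications are seed-reproducible", {
  prior <- prior_spec()
  tr1 <- build_training_set(prior, n_examples = 10,
                            sample_sizes = c(50, 100), N = 300,
                            seed = 8)
  tr2 <- build_training_set(prior, n_examples = 10,
                            sample_sizes = c(50, 100), N = 300,
                            seed = 8)
  expect_identical(tr1, tr2)
  expect_identical(nrow(tr1), 20L)
  expect_true(all(tr1$q0 <= tr1$sample_size))
  expect_true(all(tr1$q0 == round(tr1$q0)))
  expect_identical(unique(tr1$label[tr1$b == 0]), "unbiased")

  b1 <- train_classifier(tr1, num_trees = 50, seed = 9)
  b2 <- train_classifier(tr2, num_trees = 50, seed = 9)
  prof <- diversity_profile(sample_configuration(c(30, 15, 5)))
  expect_identical(classify_profile(b1, prof)$vote_fraction,
                   classify_profile(b2, prof)$vote_fraction)
})

test_that("positive frequency dependence concentrates samples", {
  # strong conformity lowers the q = 2 Hill number of samples relative to
  # unbiased transmission (paired seeds)
  q2 <- function(b, seed) {
    tab <- run_wright_fisher(2000, mu = 2e-3, b = b, seed = seed)
    mean(replicate(5, diversity_profile(sample_variants(tab, 200))[[9]]))
  }
  seeds <- 60:79
  q2_biased <- vapply(seeds, function(s) q2(5e-3, s), numeric(1))
  q2_neutral <- vapply(seeds, function(s) q2(0, s), numeric(1))
  expect_lt(mean(q2_biased), mean(q2_neutral))
})
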