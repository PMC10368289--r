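feature_names <- function(q_grid = default_q_grid()) paste0("q", q_grid)

profile_row <- function(profile) {
  v <- as.numeric(unclass(profile))
  names(v) <- feature_names(attr(profile, "q_grid"))
  v
}

#' Build a labelled training set of diversity profiles
#'
#' Runs `n_examples` independent simulations with parameters drawn from the
#' training prior, takes one random sample per requested sample size from
#' each steady-state population, and records the Hill-number diversity
#' profile of every sample together with its transmission label
#' (`"unbiased"` iff the drawn `b` is exactly 0) and the generating
#' parameters.  Reusing each simulated population across sample sizes
#' mirrors training separate per-sample-size classifiers on a shared
#' simulation budget.
#'
#' @param prior A [prior_spec()].
#' @param n_examples Number of simulations (>= 10).
#' @param sample_sizes Sample sizes drawn from each population.
#' @param N Population size of the training simulations.  The full-scale
#'   setting is `1e5`; smaller values give desk-scale training sets.
#' @param seed Optional integer seed.
#' @param max_skip_frac Simulations whose burn-in diagnostic fails are
#'   skipped; error if more than this fraction is skipped.
#' @return A data frame with the 13 feature columns `q0 ... q3`, plus
#'   `label`, `sample_size`, `example`, `b`, `mu`, `p_death`, `c_thresh`.
#' @export
build_training_set <- function(prior, n_examples, sample_sizes = c(100L,
                               500L, 1000L, 2000L), N = 1e5, seed = NULL,
                               max_skip_frac = 0.05) {
  stopifnot(inherits(prior, "prior_spec"), n_examples >= 10)
  if (!is.null(seed)) set.seed(seed)
  sample_sizes <- sort(unique(as.integer(sample_sizes)))
  if (any(sample_sizes > N)) {
    stop("sample sizes must not exceed N", call. = FALSE)
  }
  rows <- vector("list", n_examples * length(sample_sizes))
  skipped <- 0L
  ri <- 0L
  for (ex in seq_len(n_examples)) {
    draw <- draw_training_params(prior, N)
    ss <- tryCatch(run_to_steady_state(draw$params),
                   agedrift_nonstationary = function(e) NULL)
    if (is.null(ss)) {
      skipped <- skipped + 1L
      next
    }
    for (n in sample_sizes) {
      prof <- diversity_profile(sample_variants(ss, n))
      ri <- ri + 1L
      rows[[ri]] <- c(
        profile_row(prof),
        list(label = draw$label, sample_size = n, example = ex,
             b = draw$params$b, mu = draw$params$mu,
             p_death = draw$params$p_death,
             c_thresh = if (is_all_pool(draw$params$c_thresh)) "ALL"
                        else as.character(draw$params$c_thresh)))
    }
  }
  if (skipped > max_skip_frac * n_examples) {
    stop(sprintf("%d of %d training simulations failed to reach steady state",
                 skipped, n_examples), call. = FALSE)
  }
  if (skipped > 0L) {
    message(sprintf("skipped %d non-stationary training simulation(s)",
                    skipped))
  }
  out <- do.call(rbind, lapply(rows[seq_len(ri)], function(r) {
    as.data.frame(as.list(r), check.names = FALSE,
                  stringsAsFactors = FALSE)
  }))
  fn <- feature_names()
  out[fn] <- lapply(out[fn], as.numeric)
  out$sample_size <- as.integer(out$sample_size)
  out$example <- as.integer(out$example)
  for (col in c("b", "mu", "p_death")) out[[col]] <- as.numeric(out[[col]])
  rownames(out) <- NULL
  out
}

#' Train per-sample-size random-forest classifiers
#'
#' Fits one random forest (bootstrap-resampled trees with random feature
#' subsetting at each split, majority vote across the `num_trees` trees)
#' per sample size present in the training set, using the 13 diversity
#' profile values as features and the unbiased/biased label as response.
#' A stratified 20% held-out split per sample size provides an accuracy
#' estimate and the development set for [permutation_importance()].
#'
#' @param training A training-set data frame from [build_training_set()]
#'   (or [read_training_csv()]).
#' @param num_trees Trees per forest (default 500).
#' @param mtry Features tried per split; default `floor(sqrt(13)) = 3`.
#' @param holdout_frac Fraction held out per sample size (default 0.2).
#' @param seed Optional integer seed (controls the split and the forests).
#' @return An object of class `"classifier_bundle"`: per-sample-size
#'   `ranger` forests, held-out rows, held-out accuracies and metadata.
#' @importFrom ranger ranger
#' @export
train_classifier <- function(training, num_trees = 500, mtry = NULL,
                             holdout_frac = 0.2, seed = NULL) {
  fn <- feature_names()
  stopifnot(all(fn %in% names(training)),
            all(c("label", "sample_size") %in% names(training)))
  if (length(unique(training$label)) < 2L) {
    stop("training set must contain both labels", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mtry)) mtry <- floor(sqrt(length(fn)))
  sizes <- sort(unique(training$sample_size))
  forests <- list()
  heldout <- list()
  accuracy <- numeric(0)
  for (n in sizes) {
    dat <- training[training$sample_size == n, , drop = FALSE]
    # stratified holdout split
    test_idx <- unlist(lapply(split(seq_len(nrow(dat)), dat$label),
                              function(ix) {
      sample(ix, max(1L, round(holdout_frac * length(ix))))
    }), use.names = FALSE)
    train_dat <- dat[-test_idx, , drop = FALSE]
    test_dat <- dat[test_idx, , drop = FALSE]
    if (length(unique(train_dat$label)) < 2L) {
      stop(sprintf("single-class training data for sample size %d", n),
           call. = FALSE)
    }
    fit <- ranger::ranger(
      x = train_dat[fn], y = factor(train_dat$label,
                                    levels = c("unbiased", "biased")),
      num.trees = num_trees, mtry = mtry,
      seed = sample.int(.Machine$integer.max, 1L))
    pred <- predict(fit, data = test_dat[fn])$predictions
    acc <- mean(pred == test_dat$label)
    forests[[as.character(n)]] <- fit
    heldout[[as.character(n)]] <- test_dat
    accuracy[as.character(n)] <- acc
  }
  structure(
    list(forests = forests, heldout = heldout,
         heldout_accuracy = accuracy, num_trees = num_trees, mtry = mtry,
         feature_names = fn, sample_sizes = sizes),
    class = "classifier_bundle")
}

#' @export
print.classifier_bundle <- function(x, ...) {
  cat(sprintf("Random-forest classifier bundle (%d trees, mtry %d)\n",
              x$num_trees, x$mtry))
  for (n in names(x$forests)) {
    cat(sprintf("  n = %-5s held-out accuracy %.3f\n", n,
                x$heldout_accuracy[n]))
  }
  invisible(x)
}

bundle_forest <- function(bundle, n) {
  fit <- bundle$forests[[as.character(n)]]
  if (is.null(fit)) {
    stop(sprintf(
      "no classifier trained for sample size %d (available: %s)", n,
      paste(bundle$sample_sizes, collapse = ", ")), call. = FALSE)
  }
  fit
}

# Vectorized biased-vote fractions for a feature matrix (rows = profiles).
vote_fractions <- function(bundle, features, n) {
  fit <- bundle_forest(bundle, n)
  votes <- predict(fit, data = features,
                   predict.all = TRUE)$predictions
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L)
  biased_level <- which(fit$forest$levels == "biased")
  rowMeans(votes == biased_level)
}

#' Classify a diversity profile as unbiased or biased
#'
#' Applies the forest trained for the profile's sample size; the label is
#' the majority vote of the trees and `vote_fraction` the fraction of
#' trees voting "biased".
#'
#' @param bundle A `"classifier_bundle"` from [train_classifier()].
#' @param profile A [diversity_profile()] (its `n` attribute selects the
#'   forest).
#' @return A list with `label` and `vote_fraction`.
#' @export
classify_profile <- function(bundle, profile) {
  stopifnot(inherits(bundle, "classifier_bundle"),
            inherits(profile, "diversity_profile"))
  feat <- matrix(profile_row(profile), nrow = 1L,
                 dimnames = list(NULL, bundle$feature_names))
  vf <- vote_fractions(bundle, feat, attr(profile, "n"))
  list(label = if (vf > 0.5) "biased" else "unbiased",
       vote_fraction = vf)
}

#' Permutation feature importance
#'
#' The drop in held-out accuracy when a single feature column is randomly
#' shuffled, averaged over `n_permutations` shuffles -- computed per
#' feature and per sample size.  Uninformative features give importances
#' near (possibly below) zero.
#'
#' @param bundle A `"classifier_bundle"`.
#' @param heldout Held-out data frame (features + `label` +
#'   `sample_size`); defaults to the bundle's own held-out split.
#' @param n_permutations Shuffles per feature (default 20).
#' @param seed Optional integer seed.
#' @return A data frame with columns `sample_size`, `q`, `importance`.
#' @export
permutation_importance <- function(bundle, heldout = NULL,
                                   n_permutations = 20, seed = NULL) {
  stopifnot(inherits(bundle, "classifier_bundle"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(heldout)) heldout <- do.call(rbind, bundle$heldout)
  fn <- bundle$feature_names
  stopifnot(all(c(fn, "label", "sample_size") %in% names(heldout)),
            nrow(heldout) > 0L)
  q_grid <- as.numeric(sub("^q", "", fn))
  out <- list()
  for (n in intersect(bundle$sample_sizes, unique(heldout$sample_size))) {
    dat <- heldout[heldout$sample_size == n, , drop = FALSE]
    fit <- bundle_forest(bundle, n)
    base_acc <- mean(predict(fit, data = dat[fn])$predictions == dat$label)
    drop <- vapply(fn, function(f) {
      accs <- vapply(seq_len(n_permutations), function(i) {
        shuffled <- dat[fn]
        shuffled[[f]] <- sample(shuffled[[f]])
        mean(predict(fit, data = shuffled)$predictions == dat$label)
      }, numeric(1))
      base_acc - mean(accs)
    }, numeric(1))
    out[[as.character(n)]] <- data.frame(sample_size = n, q = q_grid,
                                         importance = unname(drop))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
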