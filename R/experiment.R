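#' Rejection-probability experiment
#'
#' For each parameter constellation `(b, p_death, c_thresh)` in `grid`,
#' simulates `n_reps` independent populations to steady state, draws one
#' sample per requested sample size from each, applies either the
#' Ewens-Watterson test (two-tailed: rejecting when either tail sum is at
#' most `alpha / 2`) or a trained
#' classifier bundle (rejecting when the majority of trees vote "biased"),
#' and tabulates rejection fractions with exact binomial confidence
#' intervals.  Populations are reused across sample sizes within a
#' replicate.
#'
#' The Wright-Fisher comparison (no age structure) is the constellation
#' `p_death = 1`, `c_thresh = "ALL"`.
#'
#' @param grid Data frame with columns `b`, `p_death`, `c_thresh`
#'   (`"ALL"` or a positive integer, character or numeric).
#' @param n_reps Independent populations per constellation (>= 20).
#' @param sample_sizes Sample sizes drawn from each population.
#' @param method `"ewens"` or `"ml"`.
#' @param bundle A `"classifier_bundle"`; required for `method = "ml"`.
#' @param N Population size of the evaluation simulations.
#' @param mu Innovation rate of the evaluation simulations.
#' @param alpha Significance level of the Ewens-Watterson test.
#' @param mc_samples Monte-Carlo draws per Ewens-Watterson p-value.
#' @param seed Optional integer seed.
#' @return A long-format data frame: `b`, `p_death`, `c_thresh`,
#'   `sample_size`, `n_reps`, `rejections`, `rejection_fraction`,
#'   `ci_lower`, `ci_upper`.
#' @export
rejection_experiment <- function(grid, n_reps, sample_sizes,
                                 method = c("ewens", "ml"), bundle = NULL,
                                 N = 1e5, mu = 5e-4, alpha = 0.05,
                                 mc_samples = 1e5, seed = NULL) {
  method <- match.arg(method)
  stopifnot(all(c("b", "p_death", "c_thresh") %in% names(grid)),
            n_reps >= 20)
  if (method == "ml" && !inherits(bundle, "classifier_bundle")) {
    stop("`bundle` must be a classifier_bundle for method = \"ml\"",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sample_sizes <- sort(unique(as.integer(sample_sizes)))
  out <- list()
  for (g in seq_len(nrow(grid))) {
    b <- grid$b[g]
    p_death <- grid$p_death[g]
    c_thresh <- canonical_c_thresh(grid$c_thresh[g])
    params <- sim_params(N = N, mu = mu, p_death = p_death,
                         c_thresh = c_thresh, b = b)
    rejected <- matrix(NA, n_reps, length(sample_sizes),
                       dimnames = list(NULL, sample_sizes))
    features <- if (method == "ml") {
      lapply(sample_sizes, function(n) {
        matrix(NA_real_, n_reps, 13L,
               dimnames = list(NULL, feature_names()))
      })
    }
    for (r in seq_len(n_reps)) {
      ss <- run_to_steady_state(params)
      for (j in seq_along(sample_sizes)) {
        config <- sample_variants(ss, sample_sizes[j])
        if (method == "ewens") {
          pe <- ewens_watterson_test(config, mc_samples = mc_samples,
                                     alpha = alpha)
          rejected[r, j] <- pe$reject
        } else {
          features[[j]][r, ] <- profile_row(diversity_profile(config))
        }
      }
    }
    if (method == "ml") {
      for (j in seq_along(sample_sizes)) {
        vf <- vote_fractions(bundle, features[[j]], sample_sizes[j])
        rejected[, j] <- vf > 0.5
      }
    }
    for (j in seq_along(sample_sizes)) {
      x <- sum(rejected[, j])
      ci <- stats::binom.test(x, n_reps)$conf.int
      out[[length(out) + 1L]] <- data.frame(
        b = b, p_death = p_death,
        c_thresh = if (is_all_pool(c_thresh)) "ALL"
                   else as.character(c_thresh),
        sample_size = sample_sizes[j], n_reps = n_reps, rejections = x,
        rejection_fraction = x / n_reps,
        ci_lower = ci[1], ci_upper = ci[2])
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
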