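#' Prior over simulation parameters for classifier training
#'
#' Describes the distribution from which training simulations draw their
#' parameters: with probability `unbiased_fraction` the bias is exactly
#' `b = 0` (label "unbiased"), otherwise `b ~ Normal(0, b_sd)` resampled
#' until `|b| >= b_min` (label "biased"); the innovation rate is uniform,
#' `mu ~ U(mu_range)`; the death probability
#' `p_death ~ U(p_death_range)`; and the copy-pool limit `c_thresh` is
#' discrete-uniform over `{1, ..., a_max}` where `a_max` is the oldest age
#' in a pilot run of the population (so the prior spans everything from the
#' strongest age constraint to effectively none).
#'
#' @param b_sd Standard deviation of the Gaussian bias prior (default
#'   `1e-3`).
#' @param b_min Resampling floor keeping "biased" draws distinguishable
#'   from exact zero (default `1e-6`).
#' @param mu_range Interval for the innovation-rate prior (default
#'   `c(1e-5, 1e-3)`).
#' @param p_death_range Interval for the death-probability prior (default
#'   `c(0.02, 0.1)`).
#' @param unbiased_fraction Mixture weight of the exact `b = 0` component
#'   (default 0.5).
#' @return An object of class `"prior_spec"`.
#' @export
prior_spec <- function(b_sd = 1e-3, b_min = 1e-6,
                       mu_range = c(1e-5, 1e-3),
                       p_death_range = c(0.02, 0.1),
                       unbiased_fraction = 0.5) {
  stopifnot(b_sd > 0, b_min >= 0,
            length(mu_range) == 2L, mu_range[1] < mu_range[2],
            length(p_death_range) == 2L,
            p_death_range[1] <= p_death_range[2],
            p_death_range[1] > 0, p_death_range[2] <= 1,
            unbiased_fraction > 0, unbiased_fraction <= 1)
  structure(
    list(b_sd = b_sd, b_min = b_min, mu_range = mu_range,
         p_death_range = p_death_range,
         unbiased_fraction = unbiased_fraction),
    class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Training prior\n")
  cat(sprintf("  b        : 0 w.p. %.2f, else Normal(0, %g) (|b| >= %g)\n",
              x$unbiased_fraction, x$b_sd, x$b_min))
  cat(sprintf("  mu       : U(%g, %g)\n", x$mu_range[1], x$mu_range[2]))
  cat(sprintf("  p_death  : U(%g, %g)\n", x$p_death_range[1],
              x$p_death_range[2]))
  cat("  c_thresh : discrete uniform over {1, ..., a_max}\n")
  invisible(x)
}

#' Draw one parameter set (and its label) from the training prior
#'
#' The copy-pool limit is drawn after the age scale is known: `a_max` is
#' taken as the age that the stationary geometric age profile exceeds with
#' probability `1/N` (in effect the oldest individual a population of this
#' size contains), capped at `20 / p_death`; `c_thresh` is then uniform on
#' `{1, ..., a_max}`, with the top value mapped to `"ALL"` since a pool
#' reaching the oldest individual is the unconstrained scenario.
#'
#' @param prior A [prior_spec()].
#' @param N Population size for the simulation the draw parameterizes.
#' @return A list with `params` (a [sim_params()]) and `label`
#'   (`"unbiased"` or `"biased"`).
#' @export
draw_training_params <- function(prior, N) {
  stopifnot(inherits(prior, "prior_spec"))
  if (runif(1) < prior$unbiased_fraction) {
    b <- 0
    label <- "unbiased"
  } else {
    repeat {
      b <- rnorm(1, 0, prior$b_sd)
      if (abs(b) >= prior$b_min) break
    }
    label <- "biased"
  }
  mu <- runif(1, prior$mu_range[1], prior$mu_range[2])
  p_death <- runif(1, prior$p_death_range[1], prior$p_death_range[2])
  # oldest age present at stationarity: P(age > a) = (1-p)^a = 1/N
  a_max <- if (p_death >= 1) 1L else
    min(ceiling(log(1 / N) / log(1 - p_death)),
        ceiling(20 / p_death))
  ct <- sample.int(a_max, 1L)
  c_thresh <- if (ct == a_max) "ALL" else ct
  list(params = sim_params(N = N, mu = mu, p_death = p_death,
                           c_thresh = c_thresh, b = b),
       label = label)
}
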