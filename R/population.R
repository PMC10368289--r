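#' @useDynLib agedrift, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rgeom runif rmultinom rnorm rhyper coef lm
#'   residuals cor sd var predict binom.test
#' @importFrom utils read.csv write.csv
NULL

new_population <- function(ages, variants, next_label, step_index = 0L) {
  structure(
    list(ages = as.integer(ages), variants = as.integer(variants),
         next_label = as.integer(next_label),
         step_index = as.integer(step_index)),
    class = "population"
  )
}

#' Initialize a population
#'
#' Creates a monomorphic starting population (every individual carries
#' variant label 0) with ages drawn i.i.d. from the stationary age profile
#' of the death process: a geometric law with success probability
#' `p_death`, truncated at `params$max_age`.  The burn-in performed by
#' [run_to_steady_state()] erases this initial condition; starting from the
#' stationary age profile merely shortens the transient.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `"population"` with fields `ages`,
#'   `variants`, `next_label` and `step_index`.
#' @examples
#' pop <- init_population(sim_params(N = 10, mu = 0, p_death = 0.5))
#' table(pop$variants)
#' @export
init_population <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  ages <- pmin(rgeom(params$N, params$p_death), params$max_age)
  new_population(ages, integer(params$N), next_label = 1L)
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("Population of %d individuals (step %d)\n",
              length(x$ages), x$step_index))
  cat(sprintf("  variant types : %d\n", length(unique(x$variants))))
  cat(sprintf("  age range     : %d..%d (mean %.1f)\n",
              min(x$ages), max(x$ages), mean(x$ages)))
  invisible(x)
}

new_variant_pool <- function(labels, counts) {
  keep <- counts > 0L
  structure(
    list(labels = as.integer(labels[keep]), counts = as.integer(counts[keep]),
         total = as.integer(sum(counts[keep]))),
    class = "variant_pool"
  )
}

#' Variant abundance table of a copy pool
#'
#' Tabulates the variants carried by the members of the copy pool: the
#' individuals of the *previous* time step whose age, measured at the
#' moment of copying (i.e. after the current step's aging), lies in
#' `[1, c_thresh]` -- equivalently, previous-snapshot ages `0..c_thresh-1`.
#' With `c_thresh = "ALL"` the pool is the whole previous population.
#' `c_thresh = 1` therefore restricts copying to the variants transmitted
#' in the immediately preceding step ("the most recently transmitted
#' variants"), which makes the newborn-cohort lineage a Wright-Fisher
#' chain of size about `N * p_death` -- the effective size the '1'
#' scenario exhibits.
#'
#' @param pop A `"population"` (the previous step's snapshot).
#' @param c_thresh `"ALL"` or a positive integer; see [sim_params()].
#' @return An object of class `"variant_pool"` with fields `labels`,
#'   `counts` and `total`.
#' @examples
#' pop <- init_population(sim_params(N = 50, mu = 0, p_death = 0.2))
#' copy_pool(pop, "ALL")$total
#' @export
copy_pool <- function(pop, c_thresh = "ALL") {
  stopifnot(inherits(pop, "population"))
  c_thresh <- canonical_c_thresh(c_thresh)
  in_pool <- if (is_all_pool(c_thresh)) rep(TRUE, length(pop$ages))
             else pop$ages <= c_thresh - 1L
  if (!any(in_pool)) {
    stop(sprintf(
      "empty copy pool: no individual with age (at copying) in [1, %s]",
      as.character(c_thresh)), call. = FALSE)
  }
  tab <- variant_counts(pop$variants[in_pool])
  new_variant_pool(tab$labels, tab$counts)
}

# Tabulate integer variant labels -> (labels, counts), labels sorted.
variant_counts <- function(variants) {
  tab <- table(variants)
  list(labels = as.integer(names(tab)), counts = as.integer(tab))
}

#' Full-population variant abundance table
#'
#' @param pop A `"population"`.
#' @return A `"variant_pool"` over all `N` individuals.
#' @export
population_table <- function(pop) {
  stopifnot(inherits(pop, "population"))
  tab <- variant_counts(pop$variants)
  new_variant_pool(tab$labels, tab$counts)
}

#' @export
print.variant_pool <- function(x, ...) {
  cat(sprintf("Variant pool: %d types, %d individuals\n",
              length(x$labels), x$total))
  invisible(x)
}

#' Adoption probabilities over a copy pool
#'
#' Converts a pool abundance table into the distribution from which a naive
#' newborn adopts its variant.  Variant `i` with pool count `n_i` out of
#' `N_P` is copied with probability
#' `(n_i/N_P)^(1+b) / sum_j (n_j/N_P)^(1+b) * (1 - mu)`;
#' with `b = 0` this reduces to linear (unbiased) copying
#' `n_i/N_P * (1 - mu)`.  The remaining mass `mu` is the probability of
#' innovating, i.e. adopting a brand-new variant.
#'
#' @param pool A `"variant_pool"`.
#' @param b Frequency-dependence strength (`> -1`).
#' @param mu Innovation rate in `[0, 1]`.
#' @return An object of class `"adoption_dist"` with fields `labels`,
#'   `probs` (summing to `1 - mu`) and `innovation_mass` (`= mu`).
#' @examples
#' pool <- structure(list(labels = c(1L, 2L), counts = c(60L, 40L),
#'                        total = 100L), class = "variant_pool")
#' adoption_distribution(pool, b = 1, mu = 0)$probs  # (0.36, 0.16)/0.52
#' @export
adoption_distribution <- function(pool, b = 0, mu = 0) {
  stopifnot(inherits(pool, "variant_pool"))
  if (length(pool$labels) == 0L) stop("empty copy pool", call. = FALSE)
  if (b <= -1) stop("`b` must be > -1", call. = FALSE)
  if (mu < 0 || mu > 1) stop("`mu` must lie in [0, 1]", call. = FALSE)
  f <- pool$counts / pool$total
  if (b == 0) {
    probs <- f * (1 - mu)
  } else {
    w <- f^(1 + b)
    probs <- w / sum(w) * (1 - mu)
  }
  structure(list(labels = pool$labels, probs = probs, innovation_mass = mu),
            class = "adoption_dist")
}

#' Advance the population by one time step (reference implementation)
#'
#' Pure-R, individual-level implementation of one step of the model:
#' survivors age by one; every individual (newborns of the previous step
#' included) dies independently with probability `p_death`; exactly as many
#' newborns enter at age 0 as individuals died, keeping the population size
#' at `N`; each newborn innovates with probability `mu` (taking the next
#' fresh label) and otherwise copies a role model drawn from the adoption
#' distribution over the copy pool of the *previous* step's snapshot --
#' deaths occurring this step never remove a role model from the pool.
#'
#' This function is the readable reference used by the test suite; long
#' simulations go through the compiled loop in [run_agent()].
#'
#' @param pop A `"population"` (the state at the previous step).
#' @param params A [sim_params()] object.
#' @return The population at the next step.
#' @export
step_population <- function(pop, params) {
  stopifnot(inherits(pop, "population"), inherits(params, "sim_params"))
  N <- length(pop$ages)
  pool <- copy_pool(pop, params$c_thresh)       # snapshot of prev step
  dist <- adoption_distribution(pool, params$b, params$mu)

  dies <- runif(N) < params$p_death
  n_dead <- sum(dies)
  ages <- pop$ages
  variants <- pop$variants
  ages[!dies] <- ages[!dies] + 1L
  next_label <- pop$next_label
  if (n_dead > 0L) {
    innovates <- runif(n_dead) < dist$innovation_mass
    new_variants <- integer(n_dead)
    n_copy <- sum(!innovates)
    if (n_copy > 0L) {
      idx <- sample.int(length(dist$labels), n_copy, replace = TRUE,
                        prob = dist$probs)
      new_variants[!innovates] <- dist$labels[idx]
    }
    n_innov <- n_dead - n_copy
    if (n_innov > 0L) {
      new_variants[innovates] <- seq.int(next_label,
                                         length.out = n_innov)
      next_label <- next_label + n_innov
    }
    ages[dies] <- 0L
    variants[dies] <- new_variants
  }
  new_population(ages, variants, next_label, pop$step_index + 1L)
}

#' Sample variants from a population
#'
#' Draws a simple random sample of `n` individuals *without replacement*
#' and returns the abundance configuration of their variants.
#'
#' @param x A `"population"` or a `"variant_pool"` (full-population
#'   abundance table, e.g. from [run_wright_fisher()]).
#' @param n Sample size, `1 <= n <= N`.
#' @return A [sample_configuration()] (non-increasing positive counts).
#' @examples
#' pop <- init_population(sim_params(N = 100, mu = 0, p_death = 0.5))
#' sample_variants(pop, 10)  # monomorphic start: configuration (10)
#' @export
sample_variants <- function(x, n) UseMethod("sample_variants")

#' @rdname sample_variants
#' @export
sample_variants.population <- function(x, n) {
  N <- length(x$variants)
  if (n < 1 || n > N) stop("`n` must lie in [1, N]", call. = FALSE)
  drawn <- x$variants[sample.int(N, n)]
  tab <- variant_counts(drawn)
  sample_configuration(tab$counts)
}

#' @rdname sample_variants
#' @export
sample_variants.variant_pool <- function(x, n) {
  N <- x$total
  if (n < 1 || n > N) stop("`n` must lie in [1, N]", call. = FALSE)
  # multivariate hypergeometric draw via sampling individual slots
  expanded <- rep.int(seq_along(x$counts), x$counts)
  drawn <- expanded[sample.int(N, n)]
  counts <- tabulate(drawn, nbins = length(x$counts))
  sample_configuration(counts[counts > 0L])
}
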