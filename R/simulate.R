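# ---- burn-in policy ---------------------------------------------------------

# Rough effective-size guess used only to scale the burn-in.  'ALL' pools
# drift like N/(2 - p_death) per generation of 1/p_death steps; a pool
# restricted to ages <= c shrinks the effective size towards N * p_death
# (the '1' scenario).
ne_guess <- function(N, p_death, c_thresh) {
  if (is_all_pool(c_thresh)) return(N / (2 - p_death))
  pool_frac <- 1 - (1 - p_death)^c_thresh
  max(N * p_death, N * pool_frac / (2 - p_death))
}

#' Default burn-in length in generations
#'
#' The number of generations (units of `1 / p_death` time steps) run before
#' a population is treated as stationary:
#' `min(5 / mu, 4 * Ne_guess)`, floored at 200.  The mutation term covers
#' the high-diversity regime (the initial monomorphic type decays under
#' innovation pressure as `exp(-mu t)`, so `5 / mu` shrinks it to
#' `e^-5 < 1%`, well below typical stationary frequencies); the drift term
#' covers the low-diversity regime where the stationary state is itself
#' near-monomorphic and relaxation is drift-limited.  A richness-slope
#' diagnostic is applied after the burn-in (see [run_to_steady_state()]).
#'
#' @param params A [sim_params()] object.
#' @return Number of generations (integer).
#' @export
burnin_generations <- function(params) {
  ne <- ne_guess(params$N, params$p_death, params$c_thresh)
  mu_term <- if (params$mu > 0) 5 / params$mu else Inf
  ceiling(max(200, min(mu_term, 4 * ne)))
}

# ---- frequency-table chain (WF and 'ALL' scenario) --------------------------

# Exact reduction of the agent model when the copy pool is the whole
# previous population ("ALL"): ages never influence the dynamics, so the
# variant count vector is Markov.  Each step: every individual dies with
# probability p_death (binomially per type), the D dead slots are refilled
# by newborns that innovate with probability mu and otherwise copy from the
# previous step's counts with frequency-dependent weights.  p_death = 1
# recovers the Wright-Fisher generation.  The loop runs compiled
# (src/freq_chain.cpp).
run_freq_chain <- function(labels, counts, next_label, N, mu, p_death, b,
                           n_steps, thin = 0L, stop_at_fixation = FALSE) {
  res <- run_freq_chain_cpp(as.integer(labels), as.integer(counts),
                            as.integer(next_label), as.integer(N), mu,
                            p_death, b, as.integer(n_steps),
                            as.integer(thin), stop_at_fixation)
  list(labels = res$labels, counts = res$counts,
       next_label = res$next_label,
       richness = data.frame(step = res$richness_step,
                             richness = res$richness),
       steps_done = res$steps_done)
}

#' Wright-Fisher infinite-alleles simulation (frequency-table engine)
#'
#' Efficient non-agent implementation of the model without age structure
#' (`p_death = 1`, whole-population copy pool): each generation the `N`
#' offspring are drawn jointly from the adoption distribution over the
#' parent generation's type counts, with `rbinom(1, N, mu)` of them
#' innovating new types.  Distributionally equivalent to the agent model at
#' `p_death = 1`, `c_thresh = "ALL"`.
#'
#' @param N Population size.
#' @param mu Innovation rate.
#' @param b Frequency-dependence strength.
#' @param generations Number of generations; default is the burn-in policy
#'   of [burnin_generations()].
#' @param init_counts Optional starting counts (default monomorphic).
#' @param seed Optional integer seed.
#' @param stop_at_fixation Stop as soon as a single type remains.
#' @return A `"variant_pool"` over the final generation, with attributes
#'   `labels` are in the pool object; `generations` run and a `richness`
#'   trajectory data frame.
#' @examples
#' tab <- run_wright_fisher(200, mu = 0.01, generations = 500, seed = 1)
#' length(tab$labels)
#' @export
run_wright_fisher <- function(N, mu, b = 0, generations = NULL,
                              init_counts = NULL, seed = NULL,
                              stop_at_fixation = FALSE) {
  params <- sim_params(N = N, mu = mu, p_death = 1, c_thresh = "ALL", b = b)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(generations)) generations <- burnin_generations(params)
  if (is.null(init_counts)) init_counts <- N
  init_counts <- as.integer(init_counts)
  if (sum(init_counts) != N) stop("`init_counts` must sum to N",
                                  call. = FALSE)
  labels <- seq.int(0L, length.out = length(init_counts))
  res <- run_freq_chain(labels, init_counts,
                        next_label = length(init_counts), N = N, mu = mu,
                        p_death = 1, b = b, n_steps = generations,
                        thin = max(1L, generations %/% 200L),
                        stop_at_fixation = stop_at_fixation)
  out <- new_variant_pool(res$labels, res$counts)
  attr(out, "richness") <- res$richness
  attr(out, "generations") <- res$steps_done
  attr(out, "next_label") <- res$next_label
  out
}

# ---- agent engine wrapper ---------------------------------------------------

#' Run the agent-based simulator for a fixed number of steps
#'
#' Thin wrapper over the compiled individual-level loop.  Semantics are
#' identical to iterating [step_population()]; use this for long runs.
#'
#' @param pop Starting `"population"`.
#' @param params A [sim_params()] object.
#' @param n_steps Number of time steps.
#' @param thin Record population richness every `thin` steps (0 = never).
#' @return A list with the final `population` and a `richness` trajectory
#'   data frame.
#' @export
run_agent <- function(pop, params, n_steps, thin = 0L) {
  stopifnot(inherits(pop, "population"), inherits(params, "sim_params"))
  ct <- if (is_all_pool(params$c_thresh)) -1L else params$c_thresh
  res <- run_agent_cpp(pop$ages, pop$variants, pop$next_label,
                       as.integer(n_steps), params$mu, params$p_death,
                       ct, params$b, as.integer(thin))
  list(
    population = new_population(res$ages, res$variants, res$next_label,
                                pop$step_index + as.integer(n_steps)),
    richness = data.frame(step = pop$step_index + res$richness_step,
                          richness = res$richness)
  )
}

# ---- steady state -----------------------------------------------------------

# AR(1)-adjusted t statistic for the slope of richness ~ step.  Richness
# values along a trajectory are autocorrelated; the naive OLS t statistic
# is deflated towards over-rejection, so it is shrunk by the usual
# effective-sample-size factor sqrt((1 - r1) / (1 + r1)).
richness_slope_t <- function(traj) {
  if (nrow(traj) < 8L || var(traj$richness) == 0) return(0)
  fit <- lm(richness ~ step, data = traj)
  tval <- coef(summary(fit))["step", "t value"]
  res <- residuals(fit)
  r1 <- suppressWarnings(cor(res[-1], res[-length(res)]))
  if (is.na(r1)) r1 <- 0
  r1 <- min(max(r1, -0.99), 0.99)
  tval * sqrt((1 - r1) / (1 + r1))
}

#' Run the model to its steady state
#'
#' Initializes a population ([init_population()]), runs the burn-in
#' prescribed by [burnin_generations()] (converted to time steps via
#' `1 / p_death`), and then checks stationarity: the AR(1)-adjusted t
#' statistic of the richness slope over the last quarter of the trajectory
#' must satisfy `|t| < 2`, or the drift over that window must be
#' practically negligible (< 2.5% of mean richness).  On failure the run is
#' extended by half its length, up to `max_extensions` times; persistent
#' failure raises a condition of class `"agedrift_nonstationary"` carrying
#' the diagnostics.
#'
#' Populations with an `"ALL"` copy pool (and the Wright-Fisher limit) are
#' simulated with the exact frequency-table reduction, which is much faster
#' than the agent engine and distributionally identical; age-restricted
#' pools use the compiled agent engine.
#'
#' @param params A [sim_params()] object.
#' @param seed Optional integer seed.
#' @param generations Override the burn-in length (in generations).
#' @param engine `"auto"` (default), `"agent"` or `"freq"`; `"freq"` is
#'   only valid for `c_thresh = "ALL"`.
#' @param max_extensions Number of 50% extensions attempted when the
#'   stationarity check fails.
#' @return An object of class `"steady_state"`: a list with `table` (the
#'   full-population `"variant_pool"`), `population` (agent engine only,
#'   else `NULL`), `params`, `steps`, `richness` trajectory, `engine` and
#'   `converged`.
#' @examples
#' ss <- run_to_steady_state(sim_params(500, mu = 1e-3, p_death = 0.1),
#'                           seed = 1)
#' sample_variants(ss, 50)
#' @export
run_to_steady_state <- function(params, seed = NULL, generations = NULL,
                                engine = c("auto", "agent", "freq"),
                                max_extensions = 2L) {
  stopifnot(inherits(params, "sim_params"))
  engine <- match.arg(engine)
  if (engine == "auto") {
    engine <- if (is_all_pool(params$c_thresh)) "freq" else "agent"
  }
  if (engine == "freq" && !is_all_pool(params$c_thresh)) {
    stop("the frequency-table engine requires c_thresh = \"ALL\"",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(generations)) generations <- burnin_generations(params)
  n_steps <- ceiling(generations / params$p_death)
  thin <- max(1L, n_steps %/% 200L)

  if (engine == "freq") {
    state <- list(labels = 0L, counts = params$N, next_label = 1L)
    pop <- NULL
  } else {
    pop <- init_population(params)
  }
  richness <- NULL
  steps_done <- 0L
  converged <- FALSE

  run_chunk <- function(len) {
    if (engine == "freq") {
      res <- run_freq_chain(state$labels, state$counts, state$next_label,
                            params$N, params$mu, params$p_death, params$b,
                            len, thin = thin)
      state <<- res[c("labels", "counts", "next_label")]
      traj <- res$richness
    } else {
      res <- run_agent(pop, params, len, thin = thin)
      pop <<- res$population
      traj <- res$richness  # steps already absolute via pop$step_index
    }
    traj$step <- traj$step + if (engine == "freq") steps_done else 0L
    richness <<- rbind(richness, traj)
    steps_done <<- steps_done + len
  }

  run_chunk(n_steps)
  for (try in seq_len(max_extensions + 1L)) {
    tail_traj <- richness[richness$step > 0.75 * steps_done, , drop = FALSE]
    tstat <- richness_slope_t(tail_traj)
    # practical-equivalence escape: a fitted net drift no larger than the
    # stationary fluctuation scale (or 2.5% of mean richness) is treated
    # as stationary even when statistically nonzero
    drift_ok <- if (nrow(tail_traj) < 4L) TRUE else {
      fit <- lm(richness ~ step, data = tail_traj)
      net <- abs(coef(fit)["step"]) * diff(range(tail_traj$step))
      net <= max(0.025 * mean(tail_traj$richness),
                 2.5 * sd(tail_traj$richness))
    }
    if (abs(tstat) < 2 || drift_ok) {
      converged <- TRUE
      break
    }
    if (try <= max_extensions) run_chunk(ceiling(steps_done / 2))
  }

  table <- if (engine == "freq") new_variant_pool(state$labels, state$counts)
           else population_table(pop)
  out <- structure(
    list(table = table, population = pop, params = params,
         steps = steps_done, richness = richness, engine = engine,
         converged = converged),
    class = "steady_state")
  if (!converged) {
    cond <- structure(
      class = c("agedrift_nonstationary", "error", "condition"),
      list(message = sprintf(
             "richness trajectory still trending after %d steps (|t| = %.2f)",
             steps_done, abs(tstat)),
           call = sys.call(-1), diagnostics = out))
    stop(cond)
  }
  out
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("Steady-state population (%s engine, %d steps)\n",
              x$engine, x$steps))
  cat(sprintf("  N = %d, variant types = %d\n",
              x$params$N, length(x$table$labels)))
  invisible(x)
}

#' @rdname sample_variants
#' @export
sample_variants.steady_state <- function(x, n) sample_variants(x$table, n)
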