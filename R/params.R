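#' Simulation parameters for the age-structured transmission model
#'
#' Bundles and validates all parameters of the age-structured
#' infinite-alleles cultural transmission model.  A population of constant
#' size `N` evolves in discrete time steps: every individual dies with
#' probability `p_death` each step, the dead are replaced by naive newborns,
#' and each newborn either innovates (probability `mu`, acquiring a
#' brand-new variant label) or copies a role model drawn from the *copy
#' pool* -- the individuals of the previous time step whose age lies within
#' the pool limit `c_thresh`.  Copying is frequency dependent with strength
#' `b`: variant `i` is adopted with probability proportional to
#' `(n_i/N_P)^(1+b)`, so `b = 0` is unbiased (linear) transmission, `b > 0`
#' conformity, and `b < 0` anti-conformity.
#'
#' @param N Population size (constant over time), integer >= 2.
#' @param mu Innovation rate in `[0, 1]`: the probability that a newborn
#'   introduces a previously unseen variant rather than copying.
#' @param p_death Per-step death probability in `(0, 1]`.  `p_death = 1`
#'   recovers the Wright-Fisher model (whole population replaced each step);
#'   small values produce a deep age structure with mean age
#'   `(1 - p_death) / p_death`.
#' @param c_thresh Maximum age of individuals in the copy pool.  Either the
#'   string `"ALL"` (the whole previous population, including its age-0
#'   members) or a positive integer; `c_thresh = 1` restricts role models to
#'   individuals of age exactly 1, i.e. the most recently transmitted
#'   variants.
#' @param b Frequency-dependence strength, a real number `> -1`.
#' @param max_age Hard cap on ages used when drawing the initial stationary
#'   age profile (ages are geometric with success probability `p_death`,
#'   truncated at `max_age`).  Defaults to `20 / p_death`.
#' @return An object of class `"sim_params"`.
#' @examples
#' sim_params(N = 1000, mu = 5e-4, p_death = 0.02, c_thresh = 1)
#' @export
sim_params <- function(N, mu, p_death, c_thresh = "ALL", b = 0,
                       max_age = NULL) {
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 2 ||
      N != round(N)) {
    stop("`N` must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0 || mu > 1) {
    stop("`mu` must be a probability in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(p_death) || length(p_death) != 1L || is.na(p_death) ||
      p_death <= 0 || p_death > 1) {
    stop("`p_death` must lie in (0, 1]", call. = FALSE)
  }
  c_thresh <- canonical_c_thresh(c_thresh)
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b <= -1) {
    stop("`b` must be a real number > -1 (exponent 1 + b must stay positive)",
         call. = FALSE)
  }
  if (is.null(max_age)) max_age <- ceiling(20 / p_death)
  structure(
    list(N = as.integer(N), mu = mu, p_death = p_death,
         c_thresh = c_thresh, b = b, max_age = as.integer(max_age)),
    class = "sim_params"
  )
}

# Normalize c_thresh to the string "ALL" or a positive integer.
canonical_c_thresh <- function(c_thresh) {
  if (is.character(c_thresh)) {
    if (length(c_thresh) == 1L && toupper(c_thresh) == "ALL") return("ALL")
    suppressWarnings(ct <- as.numeric(c_thresh))
    if (length(ct) == 1L && !is.na(ct)) c_thresh <- ct
    else stop("`c_thresh` must be \"ALL\" or a positive integer",
              call. = FALSE)
  }
  if (!is.numeric(c_thresh) || length(c_thresh) != 1L || is.na(c_thresh) ||
      c_thresh < 1 || c_thresh != round(c_thresh)) {
    stop("`c_thresh` must be \"ALL\" or a positive integer", call. = FALSE)
  }
  as.integer(c_thresh)
}

is_all_pool <- function(c_thresh) {
  identical(c_thresh, "ALL")
}

#' @export
print.sim_params <- function(x, ...) {
  ct <- if (is_all_pool(x$c_thresh)) "ALL (whole previous population)"
        else as.character(x$c_thresh)
  cat("Age-structured transmission model parameters\n")
  cat(sprintf("  N        : %d\n", x$N))
  cat(sprintf("  mu       : %g\n", x$mu))
  cat(sprintf("  p_death  : %g  (mean age %.1f steps)\n", x$p_death,
              (1 - x$p_death) / x$p_death))
  cat(sprintf("  c_thresh : %s\n", ct))
  cat(sprintf("  b        : %g  (%s)\n", x$b,
              if (x$b == 0) "unbiased" else if (x$b > 0)
                "positive frequency dependence" else
                "negative frequency dependence"))
  invisible(x)
}
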