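#' Hill number of order q
#'
#' The effective number of equally abundant types at sensitivity order `q`:
#' `qD = (sum_i p_i^q)^(1/(1-q))` for `q != 1`, with the `q -> 1` limit
#' `exp(-sum_i p_i log p_i)` (the exponential of Shannon entropy) used for
#' `|q - 1| < 1e-9`.  `q = 0` gives richness, `q = 2` the inverse Simpson
#' concentration; larger `q` weights common types more heavily.
#'
#' @param freqs Relative frequencies: positive, summing to 1 (within
#'   `1e-9`).
#' @param q Order, `q >= 0` (vectorized).
#' @return The Hill number(s), numeric of length `length(q)`.
#' @examples
#' hill_number(rep(0.25, 4), q = c(0, 1, 2))  # all 4
#' hill_number(c(0.5, 0.25, 0.25), q = 2)     # 1/0.375
#' @export
hill_number <- function(freqs, q) {
  if (any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-9) {
    stop("`freqs` must be positive and sum to 1", call. = FALSE)
  }
  if (any(q < 0)) stop("`q` must be >= 0", call. = FALSE)
  vapply(q, function(qq) {
    if (abs(qq - 1) < 1e-9) {
      exp(-sum(freqs * log(freqs)))
    } else {
      sum(freqs^qq)^(1 / (1 - qq))
    }
  }, numeric(1))
}

#' Default order grid for diversity profiles
#'
#' `q = 0, 0.25, ..., 3` (13 points), the feature grid used by the
#' classifier pipeline.
#' @return Numeric vector of length 13.
#' @export
default_q_grid <- function() seq(0, 3, by = 0.25)

#' Diversity profile of a sample configuration
#'
#' Converts counts to relative frequencies and evaluates Hill numbers on a
#' grid of orders.  The `q = 0` entry equals the integer richness `k`
#' exactly.  The profile (13 values by default) is the feature vector used
#' by the random-forest classifier.
#'
#' @param config A [sample_configuration()] (or positive counts).
#' @param q_grid Increasing grid of orders; default [default_q_grid()].
#' @return An object of class `"diversity_profile"`: the numeric vector of
#'   Hill numbers, with attributes `q_grid` and `n` (sample size).
#' @examples
#' diversity_profile(sample_configuration(c(10, 10, 10, 10)))  # flat at 4
#' @export
diversity_profile <- function(config, q_grid = default_q_grid()) {
  config <- sample_configuration(config)
  counts <- as.integer(config)
  vals <- hill_number(counts / sum(counts), q_grid)
  if (q_grid[1] == 0) vals[1] <- as.numeric(config_k(config))
  structure(vals, q_grid = q_grid, n = config_n(config),
            class = "diversity_profile")
}

#' @export
print.diversity_profile <- function(x, digits = 4, ...) {
  cat(sprintf("Diversity profile (n = %d)\n", attr(x, "n")))
  m <- rbind(q = attr(x, "q_grid"), qD = round(unclass(x), digits))
  colnames(m) <- rep("", ncol(m))
  print(m)
  invisible(x)
}
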