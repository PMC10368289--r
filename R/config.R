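#' Sample configuration (allele/variant count multiset)
#'
#' A sample configuration records the unordered abundance multiset
#' `(n_1, ..., n_k)` of variant types observed in a sample of size
#' `n = sum(n_i)`.  The canonical form stores counts sorted non-increasing,
#' so two samples with the same type abundances (regardless of labels or
#' order) compare equal.
#'
#' @param counts Positive integer counts, any order.
#' @return An object of class `"sample_configuration"`: the sorted integer
#'   count vector, with attributes `n` (sample size) and `k` (number of
#'   types).
#' @examples
#' sample_configuration(c(1, 3, 2))  # canonical form (3, 2, 1), n = 6, k = 3
#' @export
sample_configuration <- function(counts) {
  if (inherits(counts, "sample_configuration")) return(counts)
  if (length(counts) == 0L) {
    stop("a sample configuration needs at least one type", call. = FALSE)
  }
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 1) ||
      any(counts != round(counts))) {
    stop("counts must be positive integers", call. = FALSE)
  }
  counts <- sort(as.integer(counts), decreasing = TRUE)
  structure(counts, n = sum(counts), k = length(counts),
            class = "sample_configuration")
}

#' @export
print.sample_configuration <- function(x, ...) {
  cat(sprintf("Sample configuration: n = %d, k = %d\n",
              attr(x, "n"), attr(x, "k")))
  cat("  counts:", paste(unclass(x), collapse = " "), "\n")
  invisible(x)
}

config_n <- function(config) attr(config, "n")
config_k <- function(config) attr(config, "k")
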