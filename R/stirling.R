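.agedrift_cache <- new.env(parent = emptyenv())

# Vectorized log(exp(a) + exp(b)) robust to -Inf.
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(-abs(a - b)))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' Log unsigned Stirling numbers of the first kind
#'
#' Computes `log |S_n^k|`, the natural log of the number of permutations of
#' `n` elements with exactly `k` cycles, via the recurrence
#' `|S_{n+1}^k| = n |S_n^k| + |S_n^{k-1}|` carried out entirely in log
#' space (the raw numbers overflow double precision long before the sample
#' sizes used here).  The full triangular table up to the largest `n`
#' requested so far is cached for the session.
#'
#' @param n Sample size(s), positive integers.
#' @param k Cycle/type count(s), `1 <= k <= n` (recycled against `n`).
#' @return `log |S_n^k|` as a numeric vector.
#' @examples
#' exp(log_stirling1(4, 2))  # 11
#' log_stirling1(6, 1) - lfactorial(5)  # 0: |S_n^1| = (n-1)!
#' @export
log_stirling1 <- function(n, k) {
  if (any(n < 1) || any(k < 1) || any(k > n)) {
    stop("log_stirling1 requires 1 <= k <= n", call. = FALSE)
  }
  tab <- stirling_table(max(n))
  tab[cbind(n, k)]
}

# Triangular matrix LS[m, j] = log|S_m^j| for 1 <= j <= m <= n_max
# (entries with j > m are NA).  Grown on demand, cached.
stirling_table <- function(n_max) {
  tab <- .agedrift_cache$stirling
  if (!is.null(tab) && nrow(tab) >= n_max) return(tab)
  start <- if (is.null(tab)) 1L else nrow(tab) + 1L
  new_tab <- matrix(NA_real_, n_max, n_max)
  if (!is.null(tab)) new_tab[seq_len(nrow(tab)), seq_len(nrow(tab))] <- tab
  if (start == 1L) {
    new_tab[1L, 1L] <- 0
    start <- 2L
  }
  for (m in seq.int(start, n_max)) {
    prev <- new_tab[m - 1L, seq_len(m - 1L)]
    grown <- logaddexp(log(m - 1) + c(prev, -Inf), c(-Inf, prev))
    new_tab[m, seq_len(m)] <- grown
  }
  .agedrift_cache$stirling <- new_tab
  new_tab
}

# Completion-count table for sampling permutations of [n] with k cycles:
# logT[m, j] = log #ways to extend a partial permutation (m elements
# placed, j cycles) to n elements and k cycles.  Boundary logT[n, k] = 0.
# Recurrence: T(m, j) = T(m+1, j+1) + m * T(m+1, j).
completion_table <- function(n, k) {
  key <- paste0("ct_", n, "_", k)
  cached <- .agedrift_cache[[key]]
  if (!is.null(cached)) return(cached)
  # the tables are n x k doubles; cap the cache to a handful of them
  held <- grep("^(ct|pn)_", ls(.agedrift_cache), value = TRUE)
  if (length(held) >= 12L) rm(list = held, envir = .agedrift_cache)
  logT <- matrix(-Inf, n, k)
  logT[n, k] <- 0
  if (n > 1L) {
    for (m in seq.int(n - 1L, 1L)) {
      nxt <- logT[m + 1L, ]
      row <- logaddexp(c(nxt[-1L], -Inf), log(m) + nxt)
      if (m < k) row[seq.int(m + 1L, k)] <- -Inf
      logT[m, ] <- row
    }
  }
  .agedrift_cache[[key]] <- logT
  logT
}

# New-cycle probability table driving the conditioned configuration
# sampler: p_new[t, j] = P(element t+1 opens a new cycle | t elements
# placed, j cycles so far), for a uniform permutation of [n] with exactly
# k cycles.  Derived from the completion counts:
# p_new = T(t+1, j+1) / (T(t+1, j+1) + t * T(t+1, j)).
new_cycle_probs <- function(n, k) {
  key <- paste0("pn_", n, "_", k)
  cached <- .agedrift_cache[[key]]
  if (!is.null(cached)) return(cached)
  logT <- completion_table(n, k)
  t_seq <- seq_len(n - 1L)
  p_new <- matrix(0, n - 1L, k)
  for (j in seq_len(k)) {
    log_new <- if (j < k) logT[t_seq + 1L, j + 1L] else rep(-Inf, n - 1L)
    log_join <- log(t_seq) + logT[t_seq + 1L, j]
    p <- 1 / (1 + exp(log_join - log_new))
    p[is.infinite(log_new) & log_new < 0] <- 0
    p[is.infinite(log_join) & log_join < 0 & !is.infinite(log_new)] <- 1
    p_new[, j] <- p
  }
  .agedrift_cache[[key]] <- p_new
  p_new
}

# Number of partitions of n into exactly k positive parts (exact up to
# overflow; used as the enumeration-size guard).
count_partitions <- function(n, k) {
  if (k < 1 || k > n) return(0)
  # p(n, k) = p(n-1, k-1) + p(n-k, k)
  tab <- matrix(0, n + 1L, k + 1L)
  tab[1L, 1L] <- 1  # p(0, 0) = 1
  for (nn in seq_len(n)) {
    for (kk in seq_len(min(nn, k))) {
      tab[nn + 1L, kk + 1L] <- tab[nn, kk] + tab[nn - kk + 1L, kk + 1L]
    }
  }
  tab[n + 1L, k + 1L]
}
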