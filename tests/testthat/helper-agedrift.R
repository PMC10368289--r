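# Shared helpers for the test suite.  All fixtures are built in code.

# A population with given variant counts and ages (recycled).
make_pop <- function(counts, ages = 1L) {
  variants <- rep.int(seq_along(counts) - 1L, counts)
  n <- length(variants)
  agedrift:::new_population(rep_len(as.integer(ages), n), variants,
                            next_label = length(counts))
}

# Modal value of an integer vector.
mode_of <- function(x) as.integer(names(which.max(table(x))))

# Population-level heterozygosity 1 - sum p_i^2 of a variant_pool.
heterozygosity <- function(tab) {
  p <- tab$counts / tab$total
  1 - sum(p^2)
}
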