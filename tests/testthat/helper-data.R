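# Small random case-control datasets for fuzzing (status independent of
# genotype; both strata nonempty).  Uses the session RNG so callers control
# the seed.

rand_data <- function(n, p, levels = 0:2, miss = 0) {
  g <- matrix(sample(levels, n * p, replace = TRUE), n, p)
  if (miss > 0)
    g[sample(length(g), round(miss * length(g)))] <- NA
  mdr_data(g, status = sample(rep_len(c(1L, 0L), n)), levels = levels)
}

# Two-locus XOR dataset with a perfectly separable pattern: cases exactly
# where the two genotypes differ.
xor_data <- function(n_per_cell = 3) {
  g <- as.matrix(expand.grid(a = 0:1, b = 0:1))
  g <- g[rep(seq_len(nrow(g)), each = n_per_cell), ]
  mdr_data(g, status = as.integer(g[, 1] != g[, 2]), levels = 0:2)
}
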