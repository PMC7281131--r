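# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# Benjamini-Hochberg step-up by its textbook definition.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest rank down
  for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Minimum-rank ranking by explicit sort-and-assign.
rank_min_brute <- function(v) {
  out <- integer(length(v))
  for (i in seq_along(v)) out[i] <- sum(v < v[i]) + 1L
  out
}

# Small simulated cohort reused by several files (genotype part kept tiny).
tiny_cohort <- function(seed = 42, n = 24, G = 600, J = 40) {
  simulate_cohort(sim_config(
    K = 3, J = J, n = n, G = G, n_effect_genes = 20,
    beta_effect = 1.25, seed = seed
  ))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
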