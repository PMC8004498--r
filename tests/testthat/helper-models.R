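# Shared fixtures and small oracles for the test suite.

# Bell numbers by the Bell triangle, an independent oracle for the size of
# the partition lattice.
bell_number <- function(n) {
  row <- 1
  if (n > 1) for (k in 2:n) {
    new <- numeric(k)
    new[1] <- row[length(row)]
    for (j in 2:k) new[j] <- new[j - 1] + row[j - 1]
    row <- new
  }
  row[length(row)]
}

# The deterministic random-model suite used by the cross-solver checks:
# 25 seeded models with n <= 4 sites and at most 2 demes.
solver_suite <- function() {
  lapply(1:25, function(k) {
    generate_random_model(seed = 1000 + k,
                          n = 2 + (k %% 3),
                          alphabet_size = 2,
                          n_demes = 1 + (k %% 2),
                          support_size = 3 + (k %% 3))
  })
}

# Dirichlet recombination distribution with full support on the partition
# lattice of 1..n (every weight positive), so the conditioned partitioning
# process is always well defined.
full_support_recomb <- function(seed, n = 4, concentration = 1) {
  set.seed(seed)
  parts <- enumerate_partitions(seq_len(n))
  w <- stats::rgamma(length(parts), shape = concentration) + 1e-3
  recomb_dist(parts, w / sum(w))
}

# Sup-norm distance between a measure table and a plain array.
tab_dist <- function(m, arr) max(abs(m$table - arr))

# Fresh temporary file path with the given extension.
temp_path <- function(ext) tempfile(fileext = ext)
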