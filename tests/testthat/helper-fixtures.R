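# shared fixtures and independent oracles

# small planted two-group dataset for fast tests
small_sim <- function(seed = 1, n_genes = 300, cells_per_group = 15, ...) {
  simulate_populations(n_genes = n_genes, cells_per_group = cells_per_group,
                       seed = seed, ...)
}

named_matrix <- function(values, n, m, prefix = c("g", "s")) {
  matrix(values, n, m,
         dimnames = list(sprintf("%s%03d", prefix[1], seq_len(n)),
                         sprintf("%s%03d", prefix[2], seq_len(m))))
}

random_positive_matrix <- function(n, m, seed) {
  set.seed(seed)
  named_matrix(runif(n * m, 0.1, 10), n, m)
}

# O(m^2) pair-enumeration oracle for the Rand measure
rand_oracle <- function(test, ref) {
  m <- length(test)
  agree <- 0L
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      same_test <- test[i] == test[j]
      same_ref <- ref[i] == ref[j]
      if (same_test == same_ref) agree <- agree + 1L
    }
  }
  agree / choose(m, 2)
}

# brute-force median-of-ratios oracle (explicit loops)
size_factor_oracle <- function(m) {
  geo <- apply(m, 1, function(x) if (any(x == 0)) 0 else exp(mean(log(x))))
  ref <- which(geo > 0)
  f <- vapply(seq_len(ncol(m)), function(j) {
    median(vapply(ref, function(i) m[i, j] / geo[i], 0))
  }, 0)
  f / exp(mean(log(f)))
}
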