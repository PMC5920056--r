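# Shared fixtures and independent oracles for the test suite.

# Independent double-loop recomputation of the distinctness score
# eta(i, R) = |R| / sum_{j in R} 1/D_norm(i, j), with the zero-distance limit.
naive_sample_eta <- function(test_index, train_indices, normalized) {
  s <- 0
  for (j in train_indices) {
    d <- normalized[test_index, j]
    if (d == 0) return(0)
    s <- s + 1 / d
  }
  length(train_indices) / s
}

# Independent recomputation of normalized distances from raw coordinates.
naive_normalized <- function(x) {
  n <- nrow(x)
  raw <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      raw[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
    }
  }
  offdiag <- raw[row(raw) != col(raw)]
  d_min <- min(offdiag)
  d_max <- max(offdiag)
  nrm <- (raw - d_min) / (d_max - d_min)
  diag(nrm) <- 0
  list(raw = raw, d_min = d_min, d_max = d_max, normalized = nrm)
}

# Hand-built pairwise_distances carrier for tests that specify normalized
# distances directly.
manual_distances <- function(normalized) {
  structure(
    list(raw = normalized, d_min = 0, d_max = 1, normalized = normalized,
         condition_ids = rownames(normalized)),
    class = "pairwise_distances"
  )
}

# Small clustered dataset for partitioner tests.
small_blobs <- function(n_clusters = 2, samples_per_cluster = 10,
                        n_features = 10, separation = 10, seed = 1) {
  generate_conditions(synthetic_config(
    n_clusters = n_clusters, samples_per_cluster = samples_per_cluster,
    n_features = n_features, cluster_separation = separation,
    n_genes = 1, regulators_per_gene = 1, seed = seed))
}

# Desk-scale annealing schedule for the 180-condition reference data: a
# short high-temperature walk around the random-partition level followed by
# a compressed cooling sweep through the transition band, so the selection
# spans from the random level up toward the most distinct test sets.
desk_schedule <- function(test_size, burn_in, n_select, seed) {
  sa_config(test_size = test_size, t_initial = 0.05,
            iters_per_temperature = 200L, cooling_factor = 0.95,
            t_min = 1e-5, burn_in = burn_in, n_select = n_select,
            seed = seed)
}
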