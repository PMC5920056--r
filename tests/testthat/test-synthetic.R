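test_that("generators are fully reproducible from the seed", {
  cfg <- synthetic_config(n_clusters = 3, samples_per_cluster = 6,
                          n_features = 8, n_genes = 4, seed = 9)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$conditions, d2$conditions)
  expect_identical(d1$targets, d2$targets)
  expect_identical(d1$heldout$targets, d2$heldout$targets)
})

test_that("cluster separation controls the cluster geometry", {
  sep_ratio <- function(sep, seed) {
    g <- generate_conditions(synthetic_config(
      n_clusters = 3, samples_per_cluster = 10, n_features = 10,
      cluster_separation = sep, n_genes = 1, regulators_per_gene = 1,
      seed = seed))
    dmat <- as.matrix(dist(g$conditions))
    same <- outer(g$cluster_labels, g$cluster_labels, "==")
    diag(same) <- NA
    mean(dmat[!same & !is.na(same)]) / mean(dmat[same & !is.na(same)])
  }
  # separated clusters: between-cluster distances dominate; k-means folds
  # recover the labels exactly
  expect_gt(sep_ratio(10, 1), 2)
  blob <- small_blobs(n_clusters = 3, samples_per_cluster = 8,
                      separation = 10, seed = 3)
  coll <- clustered_kfold(blob$conditions, 3, seed = 1)
  truth_sets <- split(seq_along(blob$cluster_labels), blob$cluster_labels)
  for (p in coll$partitions) {
    expect_true(any(vapply(truth_sets, setequal, logical(1), y = p$test)))
  }
  # no separation: labels carry no geometry
  expect_lt(sep_ratio(0, 2), 1.2)
})

test_that("replicates append jittered near-duplicates and depress random-fold distinctness", {
  cfg <- synthetic_config(n_clusters = 2, samples_per_cluster = 15,
                          n_features = 10, replicate_fraction = 0.3,
                          n_genes = 1, regulators_per_gene = 1, seed = 5)
  g <- generate_conditions(cfg)
  n_base <- 30
  n_rep <- floor(0.3 * n_base)
  expect_equal(nrow(g$conditions), n_base + n_rep)
  rep_ids <- grep("_rep$", rownames(g$conditions), value = TRUE)
  expect_length(rep_ids, n_rep)
  for (rid in rep_ids) {
    orig <- sub("_rep$", "", rid)
    expect_lt(sqrt(sum((g$conditions[rid, ] - g$conditions[orig, ])^2)), 0.1)
  }

  # a condition whose near-replicate sits in the training set is dominated
  # by that single close neighbor and scores far below the rest
  d <- compute_pairwise_distances(g$conditions)
  coll <- random_kfold(nrow(g$conditions), 3, seed = 6)
  split_scores <- other_scores <- numeric(0)
  ids <- rownames(g$conditions)
  partner <- function(id) {
    if (endsWith(id, "_rep")) sub("_rep$", "", id) else paste0(id, "_rep")
  }
  for (p in coll$partitions) {
    sc <- partition_distinctness(p, d)$scores
    train_ids <- ids[p$train]
    has_partner <- vapply(names(sc), function(id) {
      partner(id) %in% train_ids
    }, logical(1))
    split_scores <- c(split_scores, sc[has_partner])
    other_scores <- c(other_scores, sc[!has_partner])
  }
  expect_gt(length(split_scores), 0)
  expect_lt(mean(split_scores), 0.25 * mean(other_scores))
})

test_that("targets are exact sparse linear functions of the TFs when noise-free", {
  cfg <- synthetic_config(n_clusters = 2, samples_per_cluster = 10,
                          n_features = 12, n_genes = 3,
                          regulators_per_gene = 4, context_shift_sd = 0,
                          noise_sd = 0, seed = 13)
  g <- generate_conditions(cfg)
  truth <- generate_targets(g$conditions, g$cluster_labels, cfg)
  for (j in seq_len(3)) {
    b <- truth$base[[j]]
    recon <- drop(g$conditions[, b$support, drop = FALSE] %*% b$beta)
    expect_equal(unname(truth$targets[, j]), unname(recon), tolerance = 1e-12)
  }
  # with context_shift_sd = 0 every cluster shares the base coefficients
  expect_equal(truth$per_cluster[[1]], truth$per_cluster[[2]])
})

test_that("held-out clusters share base regulation but fresh contexts", {
  cfg <- synthetic_config(n_clusters = 2, samples_per_cluster = 8,
                          n_features = 10, n_genes = 3, context_shift_sd = 0.8,
                          heldout_clusters = 2, seed = 17)
  g <- generate_conditions(cfg)
  truth <- generate_targets(g$conditions, g$cluster_labels, cfg)
  ho <- generate_heldout(cfg, truth)
  expect_equal(nrow(ho$conditions), 2 * 8)
  expect_equal(colnames(ho$targets), truth$gene_ids)
  expect_identical(ho, generate_heldout(cfg, truth))
  # with zero context shift and zero noise the held-out targets obey each
  # gene's base coefficients exactly
  cfg0 <- synthetic_config(n_clusters = 2, samples_per_cluster = 8,
                           n_features = 10, n_genes = 3,
                           context_shift_sd = 0, noise_sd = 0,
                           heldout_clusters = 2, seed = 17)
  g0 <- generate_conditions(cfg0)
  truth0 <- generate_targets(g0$conditions, g0$cluster_labels, cfg0)
  ho0 <- generate_heldout(cfg0, truth0)
  for (j in 1:3) {
    b <- truth0$base[[j]]
    recon <- drop(ho0$conditions[, b$support, drop = FALSE] %*% b$beta)
    expect_equal(unname(ho0$targets[, j]), unname(recon), tolerance = 1e-12)
  }
  expect_error(generate_heldout(cfg, list()), "generate_targets")
})

test_that("stronger context shift widens the in-distribution vs held-out accuracy gap", {
  gap_at <- function(shift) {
    cfg <- synthetic_config(n_clusters = 4, samples_per_cluster = 15,
                            n_features = 20, n_genes = 8,
                            regulators_per_gene = 4,
                            context_shift_sd = shift, noise_sd = 0.3,
                            heldout_clusters = 1, seed = 23)
    ds <- generate_dataset(cfg)
    spec <- regression_spec("elastic_net", seed = 1)
    rcv <- random_kfold(nrow(ds$conditions), 4, seed = 2)
    res <- evaluate_collection(ds$conditions, ds$targets, rcv, spec)
    ho_pred <- vapply(seq_len(8), function(j) {
      p <- fit_predict_partition(ds$conditions, ds$targets[, j],
                                 ds$heldout$conditions, spec)
      cor(p, ds$heldout$targets[, j])
    }, numeric(1))
    median(res$pooled_pcc) - median(ho_pred)
  }
  expect_gt(gap_at(1.5), gap_at(0) + 0.05)
})
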