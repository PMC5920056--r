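# Synthetic clustered TF-expression data with context-specific sparse
# regulatory effects. Emulates the structure distinctness-aware CV is built
# for: conditions that cluster by biological context, target genes that are
# sparse linear functions of TFs whose coefficients shift between contexts,
# and optional near-duplicate replicate conditions.

#' Configuration of the synthetic-data generator
#'
#' Defaults describe the reference simulation used throughout the package:
#' 6 well-separated Gaussian condition clusters of 30 samples in a
#' 50-dimensional TF space (centroid spacing 8 within-cluster standard
#' deviations), 20 target genes each driven by 5 regulators, per-cluster
#' coefficient perturbations of sd 0.5 and additive noise of sd 0.5.
#'
#' @param n_clusters number of condition clusters (biological contexts).
#' @param samples_per_cluster conditions per cluster.
#' @param n_features TF features.
#' @param cluster_separation centroid spacing in units of `within_sd`.
#' @param within_sd within-cluster isotropic standard deviation.
#' @param replicate_fraction fraction of conditions duplicated with jitter
#'   `0.01 * within_sd` (near-replicates), in \[0, 1).
#' @param n_genes target genes.
#' @param regulators_per_gene nonzero coefficients per gene,
#'   `<= n_features`.
#' @param context_shift_sd sd of the per-cluster perturbation added to each
#'   gene's nonzero coefficients (0 = identical regulation in every context).
#' @param noise_sd sd of the additive expression noise on targets.
#' @param heldout_clusters number of never-trained clusters generated by
#'   [generate_heldout()].
#' @param seed RNG seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_clusters = 6L, samples_per_cluster = 30L,
                             n_features = 50L, cluster_separation = 8,
                             within_sd = 1, replicate_fraction = 0,
                             n_genes = 20L, regulators_per_gene = 5L,
                             context_shift_sd = 0.5, noise_sd = 0.5,
                             heldout_clusters = 1L, seed = 1L) {
  cfg <- list(
    n_clusters = as.integer(n_clusters),
    samples_per_cluster = as.integer(samples_per_cluster),
    n_features = as.integer(n_features),
    cluster_separation = as.double(cluster_separation),
    within_sd = as.double(within_sd),
    replicate_fraction = as.double(replicate_fraction),
    n_genes = as.integer(n_genes),
    regulators_per_gene = as.integer(regulators_per_gene),
    context_shift_sd = as.double(context_shift_sd),
    noise_sd = as.double(noise_sd),
    heldout_clusters = as.integer(heldout_clusters),
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_clusters < 1L || samples_per_cluster < 1L || n_features < 1L ||
        n_genes < 1L || regulators_per_gene < 1L) {
      stop("all counts must be positive", call. = FALSE)
    }
    if (n_clusters * samples_per_cluster < 4L) {
      stop("need at least 4 conditions (n_clusters x samples_per_cluster)",
           call. = FALSE)
    }
    if (regulators_per_gene > n_features) {
      stop("regulators_per_gene exceeds n_features", call. = FALSE)
    }
    if (replicate_fraction < 0 || replicate_fraction >= 1) {
      stop("replicate_fraction must lie in [0, 1)", call. = FALSE)
    }
    if (cluster_separation < 0 || within_sd < 0 || context_shift_sd < 0 ||
        noise_sd < 0) {
      stop("separations and standard deviations must be non-negative",
           call. = FALSE)
    }
  })
  structure(cfg, class = "synthetic_config")
}

check_synthetic_config <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop("`config` must come from synthetic_config()", call. = FALSE)
  }
  invisible(config)
}

# Cluster centroids on a sphere of radius separation * within_sd / sqrt(2):
# random directions in n_features dimensions are near-orthogonal, so the
# expected pairwise centroid distance is about separation * within_sd.
draw_centroids <- function(k, p, separation, within_sd) {
  r <- separation * within_sd / sqrt(2)
  v <- matrix(stats::rnorm(k * p), k, p)
  norms <- sqrt(rowSums(v^2))
  norms[norms == 0] <- 1
  v / norms * r
}

#' Generate clustered synthetic conditions
#'
#' Draws `n_clusters` centroids with pairwise spacing of about
#' `cluster_separation * within_sd`, samples conditions as centroid plus
#' isotropic Gaussian noise, and optionally appends near-replicates
#' (duplicates jittered by `0.01 * within_sd`).
#'
#' @param config a [synthetic_config()].
#' @return list with `conditions` (matrix with ids `c001...`; replicates are
#'   suffixed `_rep`) and `cluster_labels` (integer vector).
#' @export
generate_conditions <- function(config) {
  check_synthetic_config(config)
  with_seed(config$seed, {
    k <- config$n_clusters
    p <- config$n_features
    spc <- config$samples_per_cluster
    n <- k * spc
    centroids <- draw_centroids(k, p, config$cluster_separation,
                                config$within_sd)
    labels <- rep(seq_len(k), each = spc)
    x <- centroids[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * p, sd = config$within_sd), n, p)
    rownames(x) <- sprintf("c%03d", seq_len(n))
    colnames(x) <- sprintf("tf%03d", seq_len(p))
    n_rep <- floor(config$replicate_fraction * n)
    if (n_rep > 0L) {
      idx <- sample.int(n, n_rep)
      reps <- x[idx, , drop = FALSE] +
        matrix(stats::rnorm(n_rep * p, sd = 0.01 * config$within_sd),
               n_rep, p)
      rownames(reps) <- paste0(rownames(x)[idx], "_rep")
      x <- rbind(x, reps)
      labels <- c(labels, labels[idx])
    }
    list(conditions = x, cluster_labels = labels)
  })
}

# Draw per-gene sparse base coefficients: `q` regulators per gene with
# standard-normal effect sizes.
draw_base_coefficients <- function(n_genes, n_features, q) {
  lapply(seq_len(n_genes), function(g) {
    list(support = sort(sample.int(n_features, q)),
         beta = stats::rnorm(q))
  })
}

# Per-cluster coefficients: base plus a context perturbation on the support.
perturb_coefficients <- function(base, n_clusters, shift_sd) {
  lapply(seq_len(n_clusters), function(k) {
    lapply(base, function(b) {
      list(support = b$support,
           beta = b$beta + stats::rnorm(length(b$beta), sd = shift_sd))
    })
  })
}

linear_targets <- function(x, labels, per_cluster, noise_sd, gene_ids) {
  n <- nrow(x)
  y <- matrix(0, n, length(gene_ids), dimnames = list(rownames(x), gene_ids))
  for (g in seq_along(gene_ids)) {
    for (k in unique(labels)) {
      rows <- which(labels == k)
      cf <- per_cluster[[k]][[g]]
      y[rows, g] <- x[rows, cf$support, drop = FALSE] %*% cf$beta
    }
  }
  y + matrix(stats::rnorm(length(y), sd = noise_sd), nrow(y), ncol(y))
}

#' Generate target genes as context-shifted sparse functions of the TFs
#'
#' Each gene gets a sparse base coefficient vector (`regulators_per_gene`
#' nonzeros, standard-normal values); every cluster perturbs the nonzero
#' entries by Gaussian noise of sd `context_shift_sd`, so the same gene obeys
#' a slightly different regulatory program in every context. Expression is
#' the cluster-specific linear combination of TFs plus noise of sd
#' `noise_sd`.
#'
#' @param conditions conditions matrix from [generate_conditions()].
#' @param cluster_labels integer labels aligned with `conditions` rows.
#' @param config the same [synthetic_config()].
#' @return object of class `synthetic_truth`: list with `targets`
#'   (conditions x genes matrix), `base` (per-gene support and base
#'   coefficients) and `per_cluster` (per-cluster perturbed coefficients).
#' @export
generate_targets <- function(conditions, cluster_labels, config) {
  check_synthetic_config(config)
  x <- as_condition_matrix(conditions)
  if (length(cluster_labels) != nrow(x)) {
    stop("cluster_labels must align with conditions", call. = FALSE)
  }
  with_seed(derive_seed(config$seed, 1L), {
    gene_ids <- sprintf("g%03d", seq_len(config$n_genes))
    base <- draw_base_coefficients(config$n_genes, config$n_features,
                                   config$regulators_per_gene)
    per_cluster <- perturb_coefficients(base, max(cluster_labels),
                                        config$context_shift_sd)
    y <- linear_targets(x, cluster_labels, per_cluster, config$noise_sd,
                        gene_ids)
    structure(list(targets = y, base = base, per_cluster = per_cluster,
                   gene_ids = gene_ids),
              class = "synthetic_truth")
  })
}

#' Generate held-out clusters sharing each gene's base regulation
#'
#' Emulates testing on biological contexts absent from all training folds:
#' fresh centroids and fresh per-cluster coefficient perturbations around
#' the SAME base coefficients as the training generator, so held-out
#' accuracy measures cross-context generalization of what was learned.
#'
#' @param config the [synthetic_config()] used for the training data.
#' @param truth the [generate_targets()] result holding the base
#'   coefficients.
#' @return list with `conditions`, `cluster_labels`, `targets`.
#' @export
generate_heldout <- function(config, truth) {
  check_synthetic_config(config)
  if (!inherits(truth, "synthetic_truth")) {
    stop("`truth` must come from generate_targets()", call. = FALSE)
  }
  if (config$heldout_clusters < 1L) {
    stop("heldout_clusters must be >= 1", call. = FALSE)
  }
  with_seed(derive_seed(config$seed, 2L), {
    k <- config$heldout_clusters
    p <- config$n_features
    spc <- config$samples_per_cluster
    n <- k * spc
    centroids <- draw_centroids(k, p, config$cluster_separation,
                                config$within_sd)
    labels <- rep(seq_len(k), each = spc)
    x <- centroids[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * p, sd = config$within_sd), n, p)
    rownames(x) <- sprintf("h%03d", seq_len(n))
    colnames(x) <- sprintf("tf%03d", seq_len(p))
    per_cluster <- perturb_coefficients(truth$base, k,
                                        config$context_shift_sd)
    y <- linear_targets(x, labels, per_cluster, config$noise_sd,
                        truth$gene_ids)
    list(conditions = x, cluster_labels = labels, targets = y)
  })
}

#' Generate a full synthetic dataset
#'
#' Convenience wrapper producing conditions, cluster labels, targets with
#' ground-truth coefficients, and a held-out context set from one
#' configuration.
#'
#' @param config a [synthetic_config()].
#' @return list with `conditions`, `cluster_labels`, `targets`, `truth`,
#'   `heldout` and the `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  check_synthetic_config(config)
  cond <- generate_conditions(config)
  truth <- generate_targets(cond$conditions, cond$cluster_labels, config)
  heldout <- generate_heldout(config, truth)
  list(conditions = cond$conditions, cluster_labels = cond$cluster_labels,
       targets = truth$targets, truth = truth, heldout = heldout,
       config = config)
}
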