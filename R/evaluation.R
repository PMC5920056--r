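# Evaluation harness: train regressors over partition collections and relate
# estimated accuracy (Pearson correlation, RMSD) to train/test distinctness.

pearson_or_na <- function(x, y, what = "vector") {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant ", what, ": Pearson correlation undefined, recorded as NA",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Test-set accuracy of predictions on one partition
#'
#' Pearson correlation and root-mean-square deviation between predicted and
#' measured expression over the partition's test conditions, on the original
#' expression scale. With fewer than 3 test conditions the correlation is
#' recorded as `NA`; the RMSD is always returned.
#'
#' @param partition a [cv_partition()].
#' @param targets conditions-by-genes matrix of measured expression.
#' @param predictions matrix of predicted expression for the test conditions
#'   (rows ordered by test index, columns = genes), or a vector for a single
#'   gene.
#' @return data frame with columns `gene_id`, `pcc`, `rmsd`.
#' @export
partition_accuracy <- function(partition, targets, predictions) {
  targets <- as_target_matrix(targets)
  check_partition(partition, nrow(targets))
  test <- sort(partition$test)
  if (is.vector(predictions)) predictions <- matrix(predictions, ncol = 1L)
  predictions <- as.matrix(predictions)
  if (nrow(predictions) != length(test)) {
    stop("predictions do not cover the partition's test set", call. = FALSE)
  }
  if (is.null(colnames(predictions))) {
    colnames(predictions) <- colnames(targets)[seq_len(ncol(predictions))]
  }
  genes <- colnames(predictions)
  pcc <- rmsd <- numeric(length(genes))
  for (j in seq_along(genes)) {
    y <- targets[test, genes[j]]
    yhat <- predictions[, j]
    rmsd[j] <- sqrt(mean((yhat - y)^2))
    pcc[j] <- if (length(test) < 3L) NA_real_ else {
      pearson_or_na(yhat, y, "prediction or measurement vector")
    }
  }
  data.frame(gene_id = genes, pcc = pcc, rmsd = rmsd,
             stringsAsFactors = FALSE)
}

#' Pooled out-of-fold accuracy of an exhaustive collection
#'
#' For an exhaustive K-fold collection every condition is predicted exactly
#' once, as a test sample of its own fold. Pooling these out-of-fold
#' predictions over all conditions gives one Pearson correlation per gene
#' against the measured expression.
#'
#' @param collection an exhaustive [cv_partition_collection()]
#'   (kind `rcv` or `ccv`).
#' @param targets conditions-by-genes matrix of measured expression.
#' @param predictions list with one matrix per partition (test conditions in
#'   test-index order x genes), e.g. the `predictions` field of
#'   [evaluate_collection()].
#' @return named numeric vector of per-gene Pearson correlations (`NA` where
#'   undefined, with a warning).
#' @export
pooled_cv_accuracy <- function(collection, targets, predictions) {
  targets <- as_target_matrix(targets)
  check_collection(collection, nrow(targets))
  if (!collection$kind %in% c("rcv", "ccv")) {
    stop("pooled accuracy requires an exhaustive (rcv/ccv) collection",
         call. = FALSE)
  }
  pooled <- pool_predictions(collection, predictions, nrow(targets),
                             ncol(targets))
  colnames(pooled) <- colnames(targets)
  vapply(colnames(targets), function(g) {
    pearson_or_na(pooled[, g], targets[, g], paste0("vector for gene ", g))
  }, numeric(1))
}

pool_predictions <- function(collection, predictions, n, n_genes) {
  if (length(predictions) != length(collection$partitions)) {
    stop("one prediction matrix per partition is required", call. = FALSE)
  }
  pooled <- matrix(NA_real_, n, n_genes)
  for (i in seq_along(collection$partitions)) {
    test <- sort(collection$partitions[[i]]$test)
    pred <- as.matrix(predictions[[i]])
    if (nrow(pred) != length(test)) {
      stop("prediction matrix ", i, " does not match its test fold",
           call. = FALSE)
    }
    pooled[test, ] <- pred
  }
  if (anyNA(pooled)) {
    stop("pooled predictions incomplete: some condition was never a test sample",
         call. = FALSE)
  }
  pooled
}

#' Evaluate a regression method over a partition collection
#'
#' Fits the regressor of `spec` independently for every (partition, gene)
#' task — training on the partition's training conditions, predicting its
#' test conditions — and assembles per-partition accuracy, pooled accuracy
#' (exhaustive collections), and per-partition mean distinctness. Tasks are
#' independent and seeded individually from `spec$seed`, so any execution
#' order gives identical results. Test-fold target values are used only for
#' scoring, never for fitting or normalization.
#'
#' @param conditions conditions-by-features matrix.
#' @param targets conditions-by-genes matrix, rows aligned with `conditions`.
#' @param collection a [cv_partition_collection()].
#' @param spec a [regression_spec()].
#' @param distances optional [compute_pairwise_distances()] result; when
#'   given, per-partition mean distinctness is recorded.
#' @return an object of class `cv_evaluation`: list with `method`,
#'   `collection`, `gene_ids`, `predictions` (list of test x genes matrices,
#'   one per partition), `per_partition` (data frame: `partition`, `gene_id`,
#'   `pcc`, `rmsd`), `pooled_pcc` (exhaustive collections, else `NULL`) and
#'   `distinctness` (per-partition mean eta or `NULL`).
#' @export
evaluate_collection <- function(conditions, targets, collection, spec,
                                distances = NULL) {
  x <- as_condition_matrix(conditions)
  y <- as_target_matrix(targets, x)
  check_collection(collection, nrow(x))
  if (!inherits(spec, "regression_spec")) {
    stop("`spec` must be a regression_spec()", call. = FALSE)
  }
  genes <- colnames(y)
  parts <- collection$partitions
  predictions <- vector("list", length(parts))
  per_part <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    test <- sort(p$test)
    pred <- matrix(NA_real_, length(test), length(genes),
                   dimnames = list(rownames(x)[test], genes))
    for (j in seq_along(genes)) {
      task_spec <- spec
      task_spec$seed <- derive_seed(spec$seed, i, j)
      pred[, j] <- fit_predict_partition(
        x[p$train, , drop = FALSE], y[p$train, genes[j]],
        x[test, , drop = FALSE], task_spec
      )
    }
    predictions[[i]] <- pred
    acc <- partition_accuracy(p, y, pred)
    acc$partition <- i
    per_part[[i]] <- acc
  }
  per_partition <- do.call(rbind, per_part)
  per_partition <- per_partition[, c("partition", "gene_id", "pcc", "rmsd")]
  pooled <- NULL
  if (collection$kind %in% c("rcv", "ccv")) {
    pooled <- pooled_cv_accuracy(collection, y, predictions)
  }
  eta <- NULL
  if (!is.null(distances)) {
    eta <- vapply(parts, function(p) {
      partition_distinctness(p, distances)$mean
    }, numeric(1))
  }
  structure(
    list(method = spec$method, collection = collection, gene_ids = genes,
         predictions = predictions, per_partition = per_partition,
         pooled_pcc = pooled, distinctness = eta),
    class = "cv_evaluation"
  )
}

#' @export
print.cv_evaluation <- function(x, ...) {
  cat(sprintf("cv_evaluation (%s, %s): %d partitions x %d genes\n",
              x$method, x$collection$kind, length(x$predictions),
              length(x$gene_ids)))
  if (!is.null(x$pooled_pcc)) {
    cat(sprintf("  median pooled PCC: %.3f\n",
                stats::median(x$pooled_pcc, na.rm = TRUE)))
  }
  invisible(x)
}

#' Per-partition accuracy differences between two methods
#'
#' For every partition, the per-gene vector of RMSD differences
#' (method A minus method B; negative values favor A) with quartile
#' summaries — the raw material for spectrum-resolved method comparison.
#'
#' @param results_a,results_b two [evaluate_collection()] results computed on
#'   identical partitions and genes.
#' @return list with `differences` (list per partition of named per-gene
#'   `rmsd_a - rmsd_b` vectors) and `summary` (data frame: `partition`, `q1`,
#'   `median`, `q3`, and mean distinctness if available).
#' @export
compare_methods <- function(results_a, results_b) {
  for (r in list(results_a, results_b)) {
    if (!inherits(r, "cv_evaluation")) {
      stop("inputs must be cv_evaluation objects", call. = FALSE)
    }
  }
  if (!identical(results_a$gene_ids, results_b$gene_ids)) {
    stop("gene sets differ between the two results", call. = FALSE)
  }
  pa <- results_a$collection$partitions
  pb <- results_b$collection$partitions
  if (length(pa) != length(pb) ||
      !all(vapply(seq_along(pa),
                  function(i) identical(pa[[i]]$test, pb[[i]]$test),
                  logical(1)))) {
    stop("partition collections differ between the two results", call. = FALSE)
  }
  genes <- results_a$gene_ids
  diffs <- vector("list", length(pa))
  summ <- vector("list", length(pa))
  for (i in seq_along(pa)) {
    ra <- results_a$per_partition
    rb <- results_b$per_partition
    da <- ra$rmsd[ra$partition == i][match(genes, ra$gene_id[ra$partition == i])]
    db <- rb$rmsd[rb$partition == i][match(genes, rb$gene_id[rb$partition == i])]
    d <- stats::setNames(da - db, genes)
    diffs[[i]] <- d
    q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
    summ[[i]] <- data.frame(partition = i, q1 = q[1], median = q[2], q3 = q[3])
  }
  summary <- do.call(rbind, summ)
  if (!is.null(results_a$distinctness)) {
    summary$distinctness <- results_a$distinctness
  }
  list(differences = diffs, summary = summary)
}

#' Per-gene correlation between partition distinctness and accuracy
#'
#' Spearman rank correlation (average ranks for ties) between the
#' per-partition distinctness scores and each gene's per-partition accuracy.
#' A strongly negative value means the gene's apparent predictability is an
#' artifact of test sets that resemble the training data.
#'
#' @param distinctness numeric vector of per-partition (mean) distinctness.
#' @param accuracy matrix of per-partition accuracy, partitions in rows and
#'   genes in columns (a vector is taken as a single gene).
#' @return named numeric vector of per-gene Spearman correlations; genes with
#'   constant accuracy are `NA` with a warning.
#' @export
distinctness_accuracy_correlation <- function(distinctness, accuracy) {
  if (is.vector(accuracy)) accuracy <- matrix(accuracy, ncol = 1L)
  accuracy <- as.matrix(accuracy)
  if (length(distinctness) != nrow(accuracy)) {
    stop("distinctness and accuracy must align on partitions", call. = FALSE)
  }
  if (length(distinctness) < 3L) {
    stop("need at least 3 partitions for a rank correlation", call. = FALSE)
  }
  if (is.null(colnames(accuracy))) {
    colnames(accuracy) <- paste0("g", seq_len(ncol(accuracy)))
  }
  vapply(colnames(accuracy), function(g) {
    a <- accuracy[, g]
    ok <- !is.na(a)
    if (sum(ok) < 3L || stats::sd(a[ok]) == 0 ||
        stats::sd(distinctness[ok]) == 0) {
      warning("constant or insufficient accuracy for gene ", g,
              ": Spearman correlation undefined, recorded as NA",
              call. = FALSE)
      return(NA_real_)
    }
    stats::cor(distinctness[ok], a[ok], method = "spearman")
  }, numeric(1))
}
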