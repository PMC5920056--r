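# Tab-separated expression I/O and JSON partition files.

#' Read a conditions-by-features expression matrix from TSV
#'
#' Expects a tab-separated file whose first row holds feature ids and first
#' column holds condition ids. gzip-compressed files are read transparently.
#' Use `transpose = TRUE` for the features-by-conditions dialect common to
#' TCGA/Xena exports.
#'
#' @param path file path.
#' @param transpose if `TRUE`, the file is features x conditions and is
#'   transposed after reading.
#' @return a validated numeric matrix (conditions x features).
#' @export
read_expression <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  if (ncol(df) < 2L) {
    stop("expected an id column plus at least one value column in ", path,
         call. = FALSE)
  }
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate row ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1L]
      stop(sprintf("non-numeric value in %s at row '%s', column '%s'",
                   path, ids[bad], colnames(vals)[j]), call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (isTRUE(transpose)) m <- t(m)
  as_condition_matrix(m)
}

#' Write an expression matrix as TSV
#'
#' @param x conditions-by-features matrix with dimnames.
#' @param path output path.
#' @param id_column header of the id column (default `"condition_id"`).
#' @export
write_expression <- function(x, path, id_column = "condition_id") {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a partition collection to JSON
#'
#' The file stores the collection kind, the number of conditions, the folds
#' as lists of condition ids, the generator seed and free-form metadata
#' (e.g. the annealing schedule).
#'
#' @param collection a [cv_partition_collection()].
#' @param path output path.
#' @param condition_ids character vector mapping indices to ids.
#' @param seed generator seed to record.
#' @param meta named list of extra metadata.
#' @export
write_partitions <- function(collection, path, condition_ids,
                             seed = NA_integer_, meta = list()) {
  check_collection(collection, collection$n_conditions)
  if (length(condition_ids) != collection$n_conditions) {
    stop("condition_ids must have length n_conditions", call. = FALSE)
  }
  obj <- list(
    kind = collection$kind,
    n_conditions = collection$n_conditions,
    folds = lapply(collection$partitions,
                   function(p) condition_ids[sort(p$test)]),
    seed = seed,
    meta = meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a partition collection from JSON
#'
#' Round-trips [write_partitions()] output: folds are mapped back to indices
#' against `condition_ids` and the collection invariants are re-validated
#' (exhaustive, non-overlapping folds for `rcv`/`ccv`; equal test sizes for
#' `sacv`).
#'
#' @param path JSON file written by [write_partitions()].
#' @param condition_ids character vector defining the index mapping.
#' @return a [cv_partition_collection()].
#' @export
read_partitions <- function(path, condition_ids) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- length(condition_ids)
  if (!is.null(obj$n_conditions) && obj$n_conditions != n) {
    stop("partition file was written for ", obj$n_conditions,
         " conditions, got ", n, call. = FALSE)
  }
  folds <- obj$folds
  if (is.matrix(folds)) folds <- split(folds, row(folds))
  if (!is.list(folds)) folds <- list(folds)
  folds <- unname(folds)
  parts <- lapply(folds, function(ids) {
    idx <- match(ids, condition_ids)
    if (anyNA(idx)) {
      stop("unknown condition id(s) in partition file: ",
           paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    cv_partition(idx, setdiff(seq_len(n), idx), n)
  })
  cv_partition_collection(parts, obj$kind, n)
}

#' Write a per-condition distinctness table
#'
#' One row per test condition per fold: `condition_id`, `fold_index`, `eta`.
#'
#' @param collection a [cv_partition_collection()].
#' @param distances a [compute_pairwise_distances()] result.
#' @param path output TSV path.
#' @export
write_distinctness <- function(collection, distances, path) {
  check_distances(distances)
  check_collection(collection, n_distance_conditions(distances))
  rows <- lapply(seq_along(collection$partitions), function(i) {
    sc <- partition_distinctness(collection$partitions[[i]], distances)$scores
    data.frame(condition_id = names(sc), fold_index = i, eta = unname(sc),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an evaluation result as TSV
#'
#' Columns: `gene_id`, `partition_id`, `method`, `pcc`, `rmsd`, and
#' `distinctness_mean` when recorded.
#'
#' @param result a [evaluate_collection()] result.
#' @param path output TSV path.
#' @export
write_results <- function(result, path) {
  if (!inherits(result, "cv_evaluation")) {
    stop("`result` must be a cv_evaluation", call. = FALSE)
  }
  df <- result$per_partition
  out <- data.frame(
    gene_id = df$gene_id, partition_id = df$partition,
    method = result$method, pcc = df$pcc, rmsd = df$rmsd,
    stringsAsFactors = FALSE
  )
  if (!is.null(result$distinctness)) {
    out$distinctness_mean <- result$distinctness[df$partition]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
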