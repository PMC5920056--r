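# Train/test partitions and K-fold partition collections.

#' Construct a CV partition
#'
#' A partition splits condition indices into a non-empty test set and a
#' non-empty, disjoint training set.
#'
#' @param test integer indices of test conditions.
#' @param train integer indices of training conditions.
#' @param n_conditions total number of conditions the indices refer to.
#' @return an object of class `cv_partition`.
#' @export
cv_partition <- function(test, train, n_conditions) {
  p <- structure(
    list(test = sort(unique(as.integer(test))),
         train = sort(unique(as.integer(train))),
         n_conditions = as.integer(n_conditions)),
    class = "cv_partition"
  )
  check_partition(p, p$n_conditions)
  p
}

check_partition <- function(partition, n_conditions) {
  if (!inherits(partition, "cv_partition")) {
    stop("expected a cv_partition object", call. = FALSE)
  }
  test <- partition$test
  train <- partition$train
  if (length(test) == 0L || length(train) == 0L) {
    stop("test and training sets must both be non-empty", call. = FALSE)
  }
  idx <- c(test, train)
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > n_conditions)) {
    stop("partition indices out of range 1..", n_conditions, call. = FALSE)
  }
  if (length(intersect(test, train)) > 0L) {
    stop("test and training sets overlap", call. = FALSE)
  }
  invisible(partition)
}

#' @export
print.cv_partition <- function(x, ...) {
  cat(sprintf("cv_partition: %d test / %d train of %d conditions\n",
              length(x$test), length(x$train), x$n_conditions))
  invisible(x)
}

#' Construct a CV partition collection
#'
#' For kinds `rcv` (random K-fold) and `ccv` (clustered K-fold) the test sets
#' must be mutually exclusive and exhaustive over all conditions, and each
#' partition's training set is the complement of its test set. For kind
#' `sacv` (simulated annealing) every partition must have the same test-set
#' size; exhaustiveness is not required.
#'
#' @param partitions list of [cv_partition()] objects.
#' @param kind one of `"rcv"`, `"ccv"`, `"sacv"`.
#' @param n_conditions total number of conditions.
#' @return an object of class `cv_partition_collection`.
#' @export
cv_partition_collection <- function(partitions, kind, n_conditions) {
  kind <- match.arg(kind, c("rcv", "ccv", "sacv"))
  coll <- structure(
    list(partitions = partitions, kind = kind,
         n_conditions = as.integer(n_conditions)),
    class = "cv_partition_collection"
  )
  check_collection(coll, coll$n_conditions)
  coll
}

check_collection <- function(collection, n_conditions) {
  if (!inherits(collection, "cv_partition_collection")) {
    stop("expected a cv_partition_collection object", call. = FALSE)
  }
  parts <- collection$partitions
  if (length(parts) == 0L) stop("empty partition collection", call. = FALSE)
  for (p in parts) check_partition(p, n_conditions)
  if (collection$kind %in% c("rcv", "ccv")) {
    tests <- lapply(parts, `[[`, "test")
    all_test <- unlist(tests)
    if (anyDuplicated(all_test)) {
      stop("test folds overlap in an exhaustive (", collection$kind,
           ") collection", call. = FALSE)
    }
    if (!setequal(all_test, seq_len(n_conditions))) {
      stop("test folds of an exhaustive (", collection$kind,
           ") collection do not cover all conditions", call. = FALSE)
    }
    for (p in parts) {
      if (!setequal(p$train, setdiff(seq_len(n_conditions), p$test))) {
        stop("training set is not the complement of the test fold",
             call. = FALSE)
      }
    }
  } else {
    sizes <- vapply(parts, function(p) length(p$test), integer(1))
    if (length(unique(sizes)) != 1L) {
      stop("sacv partitions must share a common test-set size", call. = FALSE)
    }
  }
  invisible(collection)
}

#' @export
print.cv_partition_collection <- function(x, ...) {
  cat(sprintf("cv_partition_collection (%s): %d partitions over %d conditions\n",
              x$kind, length(x$partitions), x$n_conditions))
  invisible(x)
}

# Build an exhaustive K-fold collection from a fold-membership vector.
collection_from_folds <- function(fold_of, kind, n_conditions) {
  folds <- sort(unique(fold_of))
  parts <- lapply(folds, function(f) {
    test <- which(fold_of == f)
    cv_partition(test, setdiff(seq_len(n_conditions), test), n_conditions)
  })
  cv_partition_collection(parts, kind, n_conditions)
}
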