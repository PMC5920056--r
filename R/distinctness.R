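# Distinctness of test conditions from training conditions: the harmonic
# mean of min-max-normalized Euclidean distances in TF-expression space.

#' Pairwise condition distances with global min-max normalization
#'
#' Computes Euclidean distances between all pairs of conditions (rows) and
#' rescales them to \[0, 1\] using the minimum and maximum over all
#' off-diagonal pairs of the full condition set. The extremes are computed
#' once on the full set and reused for every downstream partition, so
#' distinctness scores are comparable across partitions.
#'
#' @param conditions conditions-by-features numeric matrix
#'   (see [as_condition_matrix()]).
#' @param zscore if `TRUE`, features are z-scored (columns centered and
#'   scaled, zero-variance columns set to 0) before distances are computed.
#'   Default `FALSE`: distances are taken on the matrix as given.
#' @return an object of class `pairwise_distances`: a list with `raw`
#'   (symmetric distance matrix), `d_min`, `d_max` (off-diagonal extremes),
#'   `normalized` (min-max scaled matrix, zero diagonal) and
#'   `condition_ids`.
#' @examples
#' x <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)
#' compute_pairwise_distances(x)$raw[1, 2]  # 5: the 3-4-5 triangle
#' @export
compute_pairwise_distances <- function(conditions, zscore = FALSE) {
  x <- as_condition_matrix(conditions)
  if (isTRUE(zscore)) {
    mu <- colMeans(x)
    sdev <- apply(x, 2L, stats::sd)
    sdev[sdev == 0] <- Inf  # constant feature carries no distance information
    x <- sweep(sweep(x, 2L, mu, "-"), 2L, sdev, "/")
  }
  raw <- as.matrix(stats::dist(x))
  off <- raw[upper.tri(raw)]
  d_min <- min(off)
  d_max <- max(off)
  if (d_max <= d_min) {
    stop("degenerate geometry: all condition pairs are equidistant, ",
         "min-max normalization is undefined (d_min == d_max)", call. = FALSE)
  }
  normalized <- (raw - d_min) / (d_max - d_min)
  diag(normalized) <- 0
  structure(
    list(raw = raw, d_min = d_min, d_max = d_max, normalized = normalized,
         condition_ids = rownames(x)),
    class = "pairwise_distances"
  )
}

#' @export
print.pairwise_distances <- function(x, ...) {
  cat(sprintf("pairwise_distances: %d conditions, d_min = %.4g, d_max = %.4g\n",
              nrow(x$raw), x$d_min, x$d_max))
  invisible(x)
}

#' Min-max normalize a single distance
#'
#' @param d raw Euclidean distance, must lie in `[d_min, d_max]`.
#' @param d_min,d_max global distance extremes, `d_max > d_min`.
#' @return `(d - d_min) / (d_max - d_min)`, in \[0, 1\].
#' @export
normalize_distance <- function(d, d_min, d_max) {
  if (d_max <= d_min) {
    stop("d_max must exceed d_min for min-max normalization", call. = FALSE)
  }
  if (any(d < d_min) || any(d > d_max)) {
    stop("distance outside [d_min, d_max]", call. = FALSE)
  }
  (d - d_min) / (d_max - d_min)
}

n_distance_conditions <- function(distances) nrow(distances$normalized)

check_distances <- function(distances) {
  if (!inherits(distances, "pairwise_distances")) {
    stop("`distances` must come from compute_pairwise_distances()",
         call. = FALSE)
  }
  invisible(distances)
}

#' Distinctness of one test condition from a training set
#'
#' The distinctness score eta of a test condition is the harmonic mean of its
#' min-max-normalized Euclidean distances to every training condition:
#' `|R| / sum_j 1/D(i, j)`. The harmonic mean is dominated by the closest
#' training conditions, so one near-duplicate of the test condition in the
#' training set drives the score toward zero. If any normalized distance is
#' exactly 0 (a duplicate, or the globally closest pair), the score is 0, the
#' limit of the harmonic mean.
#'
#' @param test_index index of the test condition.
#' @param train_indices indices of the training conditions (must not contain
#'   `test_index`).
#' @param distances a [compute_pairwise_distances()] result.
#' @return the distinctness score, a number in \[0, 1\].
#' @export
sample_distinctness <- function(test_index, train_indices, distances) {
  check_distances(distances)
  n <- n_distance_conditions(distances)
  train_indices <- as.integer(train_indices)
  test_index <- as.integer(test_index)
  if (length(test_index) != 1L || is.na(test_index) ||
      test_index < 1L || test_index > n) {
    stop("invalid test index", call. = FALSE)
  }
  if (length(train_indices) == 0L) {
    stop("training set is empty", call. = FALSE)
  }
  if (any(is.na(train_indices)) || any(train_indices < 1L) ||
      any(train_indices > n)) {
    stop("training indices out of range", call. = FALSE)
  }
  if (test_index %in% train_indices) {
    stop("test condition appears in the training set", call. = FALSE)
  }
  nd <- distances$normalized[test_index, train_indices]
  if (any(nd == 0)) return(0)
  length(nd) / sum(1 / nd)
}

#' Per-test-sample distinctness of a CV partition
#'
#' Scores every test condition of the partition against the partition's
#' training set and summarizes the scores.
#'
#' @param partition a [cv_partition()].
#' @param distances a [compute_pairwise_distances()] result of matching
#'   dimension.
#' @return list with `scores` (named by condition id, ordered by test index),
#'   `mean` and `median`.
#' @export
partition_distinctness <- function(partition, distances) {
  check_distances(distances)
  check_partition(partition, n_distance_conditions(distances))
  test <- sort(partition$test)
  scores <- vapply(
    test, sample_distinctness, numeric(1),
    train_indices = partition$train, distances = distances
  )
  names(scores) <- distances$condition_ids[test]
  list(scores = scores, mean = mean(scores), median = stats::median(scores))
}

#' Distinctness of an exhaustive K-fold partition collection
#'
#' The collection-level score is the average distinctness over all `|C|`
#' conditions, each scored exactly once as a test sample against its own
#' fold's training set. Defined only for exhaustive, mutually exclusive
#' K-fold collections (kinds `rcv` and `ccv`); for annealed (`sacv`)
#' partitions, which need not be exhaustive, use [partition_distinctness()]
#' per partition instead.
#'
#' @inheritParams partition_distinctness
#' @param collection a [cv_partition_collection()] of kind `rcv` or `ccv`.
#' @return a single number in \[0, 1\].
#' @export
collection_distinctness <- function(collection, distances) {
  check_distances(distances)
  n <- n_distance_conditions(distances)
  check_collection(collection, n)
  if (!collection$kind %in% c("rcv", "ccv")) {
    stop("collection distinctness is defined only for exhaustive K-fold ",
         "collections (rcv/ccv); use partition_distinctness() per partition ",
         "for '", collection$kind, "' collections", call. = FALSE)
  }
  total <- 0
  for (p in collection$partitions) {
    total <- total + sum(partition_distinctness(p, distances)$scores)
  }
  total / n
}
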