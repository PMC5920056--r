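# Internal helpers shared across the package.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so package functions taking a `seed` argument never
#' disturb the user's random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-task seed below 2^31 from a root seed and task indices, so
# results are identical under any task execution order.
derive_seed <- function(seed, i, j = 0L) {
  as.integer((as.double(seed) + 1000003 * i + 7919 * j) %% 2147483647)
}

#' Validate and coerce a conditions-by-features expression matrix
#'
#' A condition matrix is a plain numeric matrix with unique row names
#' (condition ids) and unique column names (feature ids), all values finite.
#' Matrices without dimnames are given `c1..cn` / `f1..fp` labels.
#'
#' @param x numeric matrix or data frame, conditions in rows, features
#'   (e.g. transcription factors) in columns.
#' @return the validated numeric matrix.
#' @export
as_condition_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression data must be a numeric matrix (conditions x features)",
         call. = FALSE)
  }
  if (nrow(x) < 2L) stop("need at least 2 conditions", call. = FALSE)
  if (ncol(x) < 1L) stop("need at least 1 feature", call. = FALSE)
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at row %d, column %d",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("c", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate condition ids", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicate feature ids", call. = FALSE)
  x
}

#' Validate a target matrix against its companion condition matrix
#'
#' @param y numeric matrix or data frame, conditions in rows, target genes in
#'   columns.
#' @param conditions optional companion condition matrix; when given, row
#'   count (and row names, if both are named) must align.
#' @return the validated numeric matrix.
#' @export
as_target_matrix <- function(y, conditions = NULL) {
  if (is.data.frame(y)) y <- as.matrix(y)
  if (is.vector(y) && is.numeric(y)) y <- matrix(y, ncol = 1L)
  if (!is.matrix(y) || !is.numeric(y)) {
    stop("targets must be a numeric matrix (conditions x genes)", call. = FALSE)
  }
  if (!all(is.finite(y))) stop("non-finite target value", call. = FALSE)
  if (is.null(colnames(y))) colnames(y) <- paste0("g", seq_len(ncol(y)))
  if (anyDuplicated(colnames(y))) stop("duplicate gene ids", call. = FALSE)
  if (!is.null(conditions)) {
    if (nrow(y) != nrow(conditions)) {
      stop("targets and conditions disagree on the number of conditions",
           call. = FALSE)
    }
    if (!is.null(rownames(y)) && !is.null(rownames(conditions)) &&
        !identical(rownames(y), rownames(conditions))) {
      stop("target rows are not in the same condition order as the expression matrix",
           call. = FALSE)
    }
  }
  y
}
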