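# Partition generators: random K-fold (RCV), clustered K-fold (CCV), and
# simulated-annealing partitions of controlled distinctness (SACV).

#' Random K-fold partition collection (RCV)
#'
#' Uniformly random, mutually exclusive, exhaustive split into `k` folds of
#' sizes differing by at most one.
#'
#' @param n_conditions number of conditions.
#' @param k number of folds, `2 <= k <= n_conditions`.
#' @param seed RNG seed; the same `(n_conditions, k, seed)` always yields the
#'   same collection.
#' @return a [cv_partition_collection()] of kind `"rcv"`.
#' @export
random_kfold <- function(n_conditions, k, seed) {
  n <- as.integer(n_conditions)
  k <- as.integer(k)
  if (k < 2L || k > n) {
    stop("k must satisfy 2 <= k <= n_conditions", call. = FALSE)
  }
  fold_of <- with_seed(seed, {
    sizes <- rep(n %/% k, k)
    if (n %% k > 0L) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
    f <- integer(n)
    f[sample.int(n)] <- rep(seq_len(k), times = sizes)
    f
  })
  collection_from_folds(fold_of, "rcv", n)
}

# k-means++ seeding: first center uniform, subsequent centers with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2L, x[centers[1L], ], "-")^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      centers[j] <- sample.int(n, 1L)
    } else {
      centers[j] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2L, x[centers[j], ], "-")^2))
  }
  x[centers, , drop = FALSE]
}

#' Clustered K-fold partition collection (CCV)
#'
#' Runs k-means on the condition feature vectors and uses each cluster as one
#' test fold, forcing test conditions to be distinct from the training
#' conditions they are scored against. Fold sizes may be unequal. Uses
#' k-means++ seeding and Hartigan-Wong iterations (up to 300).
#'
#' @param conditions conditions-by-features numeric matrix.
#' @param k number of clusters/folds, `2 <= k < n_conditions`.
#' @param seed RNG seed controlling the k-means initialization.
#' @return a [cv_partition_collection()] of kind `"ccv"`.
#' @export
clustered_kfold <- function(conditions, k, seed) {
  x <- as_condition_matrix(conditions)
  n <- nrow(x)
  k <- as.integer(k)
  if (k < 2L || k >= n) {
    stop("k must satisfy 2 <= k < n_conditions", call. = FALSE)
  }
  fold_of <- with_seed(seed, {
    fit <- NULL
    for (attempt in 1:10) {
      centers <- kmeanspp_centers(x, k)
      fit <- tryCatch(
        stats::kmeans(x, centers = centers, iter.max = 300L),
        error = function(e) NULL
      )
      if (!is.null(fit) && all(tabulate(fit$cluster, k) > 0L)) break
      fit <- NULL
    }
    if (is.null(fit)) {
      stop("k-means produced an empty cluster in 10 initializations; ",
           "reduce k or check for duplicated conditions", call. = FALSE)
    }
    fit$cluster
  })
  collection_from_folds(fold_of, "ccv", n)
}

#' Simulated-annealing configuration
#'
#' Schedule and sampling parameters for [sacv_generate()]. The defaults are
#' the full annealing schedule used on genome-scale data: initial temperature
#' 1, 500 proposals per temperature level, cooling factor 0.98 down to 1e-14,
#' the first 50000 accepted partitions discarded as burn-in, and 30 partitions
#' sampled uniformly from the remainder.
#'
#' @param test_size number of test conditions per partition.
#' @param t_initial initial temperature.
#' @param iters_per_temperature proposals at each temperature level.
#' @param cooling_factor multiplicative temperature decay per level, in (0,1).
#' @param t_min final temperature; the schedule stops once the temperature
#'   falls below it.
#' @param burn_in accepted states discarded before sampling.
#' @param n_select number of partitions sampled (uniformly, without
#'   replacement, by acceptance index) from the post-burn-in accepted states.
#' @param seed RNG seed.
#' @return an object of class `sa_config`.
#' @export
sa_config <- function(test_size, t_initial = 1, iters_per_temperature = 500L,
                      cooling_factor = 0.98, t_min = 1e-14,
                      burn_in = 50000L, n_select = 30L, seed = 1L) {
  cfg <- list(
    test_size = as.integer(test_size),
    t_initial = as.double(t_initial),
    iters_per_temperature = as.integer(iters_per_temperature),
    cooling_factor = as.double(cooling_factor),
    t_min = as.double(t_min),
    burn_in = as.integer(burn_in),
    n_select = as.integer(n_select),
    seed = as.integer(seed)
  )
  if (cfg$test_size < 1L) stop("test_size must be positive", call. = FALSE)
  if (cfg$iters_per_temperature < 1L) {
    stop("iters_per_temperature must be positive", call. = FALSE)
  }
  if (cfg$cooling_factor <= 0 || cfg$cooling_factor >= 1) {
    stop("cooling_factor must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$t_min >= cfg$t_initial) {
    stop("t_min must be below t_initial", call. = FALSE)
  }
  if (cfg$burn_in < 0L) stop("burn_in must be non-negative", call. = FALSE)
  if (cfg$n_select < 1L) stop("n_select must be positive", call. = FALSE)
  structure(cfg, class = "sa_config")
}

#' Generate CV partitions of gradually increasing distinctness (SACV)
#'
#' Anneals fixed-size test sets toward high mean distinctness. Starting from
#' a random test set, each proposal swaps one uniformly chosen test condition
#' with one uniformly chosen training condition; the objective is the mean
#' per-test-sample distinctness of the partition. Moves are accepted by the
#' Metropolis rule: improvements always, worsening moves with probability
#' `exp(delta / T)`. The temperature drops by `cooling_factor` every
#' `iters_per_temperature` proposals until it falls below `t_min`. Every
#' accepted state (including the random initial state) is recorded; after
#' discarding the first `burn_in` accepted states, `n_select` states are
#' sampled uniformly without replacement and returned ordered by acceptance
#' step, so distinctness trends upward across the selection.
#'
#' @param conditions optional conditions-by-features matrix; used only to
#'   compute `distances` when that argument is missing.
#' @param distances a [compute_pairwise_distances()] result.
#' @param config an [sa_config()].
#' @return a list with `collection` (a [cv_partition_collection()] of kind
#'   `"sacv"`), `trace` (data frame over accepted states: `step` = proposal
#'   index, `temperature`, `eta` = partition mean distinctness, `selected`),
#'   and `n_accepted`.
#' @export
sacv_generate <- function(conditions = NULL, distances = NULL, config) {
  if (!inherits(config, "sa_config")) {
    stop("`config` must be an sa_config()", call. = FALSE)
  }
  if (is.null(distances)) {
    if (is.null(conditions)) {
      stop("provide `distances` or `conditions`", call. = FALSE)
    }
    distances <- compute_pairwise_distances(conditions)
  }
  check_distances(distances)
  nd <- distances$normalized
  n <- nrow(nd)
  m <- config$test_size
  if (m >= n) {
    stop("test_size must leave at least one training condition", call. = FALSE)
  }

  inv <- 1 / nd              # finite part of the inverse distances
  zero <- nd == 0            # zero-distance pairs contribute eta = 0
  inv[zero] <- 0
  row_inv <- rowSums(inv)    # over all conditions (self term is 0)
  row_zero <- rowSums(zero)  # includes the diagonal

  # eta per test condition from finite inverse-sums and zero counts over a
  # training set of size n - m; any zero distance forces eta = 0
  eta_of <- function(s, z) {
    e <- (n - m) / s
    e[z > 0] <- 0
    e
  }

  state <- with_seed(config$seed, {
    test <- sort(sample.int(n, m))
    in_test <- logical(n); in_test[test] <- TRUE
    # per current test member: inverse-distance sum and zero count over train
    sums <- row_inv[test] - rowSums(inv[test, test, drop = FALSE])
    zcts <- row_zero[test] - rowSums(zero[test, test, drop = FALSE])
    obj <- mean(eta_of(sums, zcts))

    n_levels <- 1L + max(0L, ceiling(
      log(config$t_min / config$t_initial) / log(config$cooling_factor)))
    max_acc <- n_levels * config$iters_per_temperature + 1L
    acc_test <- vector("list", max_acc)
    acc_step <- integer(max_acc)
    acc_temp <- numeric(max_acc)
    acc_eta <- numeric(max_acc)
    acc_test[[1L]] <- test
    acc_temp[1L] <- config$t_initial
    acc_eta[1L] <- obj
    n_acc <- 1L

    temp <- config$t_initial
    step <- 0L
    while (temp >= config$t_min) {
      for (it in seq_len(config$iters_per_temperature)) {
        step <- step + 1L
        a_pos <- sample.int(m, 1L)          # leaves the test set
        a <- test[a_pos]
        pool_train <- which(!in_test)
        b <- pool_train[sample.int(length(pool_train), 1L)]  # joins test
        new_sums <- sums - inv[test, b] + inv[test, a]
        new_zcts <- zcts - zero[test, b] + zero[test, a]
        # incoming member b: scored against the new training set
        keep <- test[-a_pos]
        b_sum <- row_inv[b] - sum(inv[b, keep]) - inv[b, b]
        b_zct <- row_zero[b] - sum(zero[b, keep]) - 1L  # drop diagonal
        new_sums[a_pos] <- b_sum
        new_zcts[a_pos] <- b_zct
        new_obj <- mean(eta_of(new_sums, new_zcts))
        delta <- new_obj - obj
        if (delta >= 0 || stats::runif(1L) < exp(delta / temp)) {
          test[a_pos] <- b
          in_test[a] <- FALSE
          in_test[b] <- TRUE
          sums <- new_sums
          zcts <- new_zcts
          obj <- new_obj
          n_acc <- n_acc + 1L
          acc_test[[n_acc]] <- sort(test)
          acc_step[n_acc] <- step
          acc_temp[n_acc] <- temp
          acc_eta[n_acc] <- obj
        }
      }
      temp <- temp * config$cooling_factor
    }

    if (n_acc <= config$burn_in + config$n_select) {
      stop(sprintf(paste0(
        "only %d accepted states; need more than burn_in + n_select = %d. ",
        "Lengthen the schedule (smaller t_min or cooling_factor closer to 1) ",
        "or reduce burn_in/n_select"),
        n_acc, config$burn_in + config$n_select), call. = FALSE)
    }
    pool <- seq.int(config$burn_in + 1L, n_acc)
    picked <- sort(pool[sample.int(length(pool), config$n_select)])
    list(acc_test = acc_test[seq_len(n_acc)],
         acc_step = acc_step[seq_len(n_acc)],
         acc_temp = acc_temp[seq_len(n_acc)],
         acc_eta = acc_eta[seq_len(n_acc)], picked = picked)
  })

  parts <- lapply(state$acc_test[state$picked], function(test) {
    cv_partition(test, setdiff(seq_len(n), test), n)
  })
  collection <- cv_partition_collection(parts, "sacv", n)
  trace <- data.frame(
    step = state$acc_step,
    temperature = state$acc_temp,
    eta = state$acc_eta
  )
  trace$selected <- seq_len(nrow(trace)) %in% state$picked
  list(collection = collection, trace = trace, n_accepted = nrow(trace))
}
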