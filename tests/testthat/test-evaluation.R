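test_that("an identifiable linear signal is recovered to numerical precision", {
  set.seed(21)
  x <- matrix(rnorm(120 * 10), 120, 10)
  beta <- c(1.5, -2, 0.8, rep(0, 7))
  y <- drop(x %*% beta)
  spec <- regression_spec("elastic_net",
                          grid = list(lambda = c(1, 0.1, 1e-4, 1e-8)),
                          seed = 1)
  pred <- fit_predict_partition(x[1:100, ], y[1:100], x[101:120, ], spec)
  expect_lt(sqrt(mean((pred - y[101:120])^2)), 1e-6)
})

test_that("a pure-intercept relationship predicts the training mean", {
  x <- matrix(1, 30, 4)  # all features constant -> dropped
  y <- rnorm(30, mean = 3)
  suppressWarnings(
    pred <- fit_predict_partition(x[1:25, ], y[1:25], x[26:30, ],
                                  regression_spec("elastic_net", seed = 1))
  )
  expect_equal(unname(pred), rep(mean(y[1:25]), 5))
})

test_that("fitting is deterministic given the seed and rejects degenerate targets", {
  set.seed(31)
  x <- matrix(rnorm(40 * 6), 40, 6)
  y <- drop(x %*% rnorm(6)) + rnorm(40, sd = 0.2)
  for (method in c("lars", "elastic_net", "svr_rbf")) {
    spec <- regression_spec(method, seed = 7)
    p1 <- fit_predict_partition(x[1:30, ], y[1:30], x[31:40, ], spec)
    p2 <- fit_predict_partition(x[1:30, ], y[1:30], x[31:40, ], spec)
    expect_identical(p1, p2)
  }
  expect_error(
    fit_predict_partition(x[1:30, ], rep(2, 30), x[31:40, ],
                          regression_spec("lars")),
    "zero-variance target")
})

test_that("pooled accuracy is the per-gene Pearson correlation of out-of-fold predictions", {
  set.seed(41)
  y <- matrix(rnorm(9 * 2), 9, 2, dimnames = list(NULL, c("g1", "g2")))
  coll <- random_kfold(9, 3, seed = 1)
  perfect <- lapply(coll$partitions, function(p) y[sort(p$test), , drop = FALSE])
  expect_equal(pooled_cv_accuracy(coll, y, perfect),
               c(g1 = 1, g2 = 1))
  negated <- lapply(perfect, function(m) -m)
  expect_equal(pooled_cv_accuracy(coll, y, negated),
               c(g1 = -1, g2 = -1))

  # hand case against the explicit product-moment formula
  pred <- lapply(coll$partitions, function(p) {
    matrix(seq_along(p$test) + min(p$test) / 10, ncol = 1,
           dimnames = list(NULL, "g1"))
  })
  pooled <- numeric(9)
  for (i in 1:3) pooled[sort(coll$partitions[[i]]$test)] <- pred[[i]]
  v <- y[, 1]
  r_hand <- (sum(pooled * v) - 9 * mean(pooled) * mean(v)) /
    ((9 - 1) * sd(pooled) * sd(v))
  expect_equal(unname(pooled_cv_accuracy(coll, y[, 1, drop = FALSE], pred)),
               r_hand, tolerance = 1e-12)
})

test_that("partition accuracy returns RMSD on the original scale and a shift-invariant PCC", {
  set.seed(51)
  y <- matrix(rnorm(10), 10, 1, dimnames = list(NULL, "g1"))
  p <- cv_partition(1:5, 6:10, 10)
  perfect <- partition_accuracy(p, y, y[1:5, , drop = FALSE])
  expect_equal(perfect$rmsd, 0)
  expect_equal(perfect$pcc, 1)

  shifted <- partition_accuracy(p, y, y[1:5, , drop = FALSE] + 0.7)
  expect_equal(shifted$rmsd, 0.7)
  expect_equal(shifted$pcc, 1)

  # 5-point hand computation
  yhat <- c(0.2, -1, 0.5, 2, 1.3)
  acc <- partition_accuracy(p, y, matrix(yhat, ncol = 1))
  expect_equal(acc$rmsd, sqrt(mean((yhat - y[1:5, 1])^2)), tolerance = 1e-12)
  expect_equal(acc$pcc, cor(yhat, y[1:5, 1]), tolerance = 1e-12)

  tiny <- cv_partition(1:2, 3:10, 10)
  acc2 <- partition_accuracy(tiny, y, matrix(c(1, 2), ncol = 1))
  expect_true(is.na(acc2$pcc))
  expect_false(is.na(acc2$rmsd))
})

test_that("method comparison returns zero differences for identical results and errors on mismatches", {
  set.seed(61)
  x <- matrix(rnorm(24 * 5), 24, 5)
  y <- matrix(drop(x %*% rnorm(5)) + rnorm(24, sd = 0.3), ncol = 1,
              dimnames = list(NULL, "g1"))
  rownames(y) <- rownames(x) <- paste0("c", 1:24)
  coll <- random_kfold(24, 3, seed = 2)
  spec <- regression_spec("elastic_net", seed = 3)
  a <- evaluate_collection(x, y, coll, spec)
  b <- evaluate_collection(x, y, coll, spec)
  cmp <- compare_methods(a, b)
  expect_true(all(unlist(cmp$differences) == 0))
  expect_equal(cmp$summary$median, rep(0, 3))

  b_shift <- b
  b_shift$per_partition$rmsd <- b_shift$per_partition$rmsd + 1
  cmp2 <- compare_methods(a, b_shift)
  expect_true(all(abs(unlist(cmp2$differences) + 1) < 1e-12))

  other <- evaluate_collection(x, y, random_kfold(24, 3, seed = 99), spec)
  expect_error(compare_methods(a, other), "collections differ")
})

test_that("distinctness-accuracy correlation is a tie-aware Spearman coefficient", {
  eta <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  expect_equal(unname(distinctness_accuracy_correlation(
    eta, rev(seq_along(eta)))), -1)
  expect_equal(unname(distinctness_accuracy_correlation(
    eta, seq_along(eta))), 1)

  # 6 points with one tied pair: average-rank hand computation gives
  # -17 / sqrt(297.5)
  acc <- c(0.9, 0.8, 0.8, 0.6, 0.5, 0.4)
  expect_equal(unname(distinctness_accuracy_correlation(eta, acc)),
               -17 / sqrt(297.5), tolerance = 1e-12)

  expect_warning(
    r <- distinctness_accuracy_correlation(eta, rep(0.5, 6)),
    "constant")
  expect_true(is.na(r))
  expect_error(distinctness_accuracy_correlation(eta[1:2], acc[1:2]),
               "at least 3")
})

test_that("test-fold targets never leak into fitting", {
  set.seed(71)
  x <- matrix(rnorm(30 * 6), 30, 6)
  rownames(x) <- paste0("c", 1:30)
  y <- matrix(drop(x %*% rnorm(6)) + rnorm(30, sd = 0.3), ncol = 1,
              dimnames = list(rownames(x), "g1"))
  coll <- random_kfold(30, 3, seed = 4)
  spec <- regression_spec("elastic_net", seed = 5)
  r1 <- evaluate_collection(x, y, coll, spec)

  y_shuffled <- y
  fold1 <- sort(coll$partitions[[1]]$test)
  y_shuffled[fold1, 1] <- y[sample(fold1), 1]
  r2 <- evaluate_collection(x, y_shuffled, coll, spec)
  # fold 1's training data are untouched, so its predictions are bit-identical
  expect_identical(r1$predictions[[1]], r2$predictions[[1]])
})
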