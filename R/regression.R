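# Expression-to-expression regressors: a gene's expression is predicted from
# the TF expression vector of the same condition. Sparse linear fits go
# through glmnet; RBF support vector regression through e1071.

#' Specify a regression method and its hyperparameter search
#'
#' @param method `"lars"` (least-angle-style sparse linear model on the lasso
#'   path, tuning the number of active predictors), `"elastic_net"` (tuning
#'   penalty strength and mixing), or `"svr_rbf"` (epsilon-SVR with Gaussian
#'   kernel at fixed conventional settings).
#' @param inner_cv_folds folds of the inner CV used to choose
#'   hyperparameters on the training set (lars and elastic_net only).
#' @param grid optional named list overriding the default search space:
#'   `df` (lars: candidate active-set sizes, default `c(1, 2, 5, 10, 20, 50)`),
#'   `alpha` (elastic_net mixing, default `c(0.1, 0.5, 0.9)`), `n_lambda`
#'   (points on each log-spaced penalty path, default 20) or `lambda` (an
#'   explicit penalty grid), `cost`/`gamma`/`epsilon` (svr_rbf; defaults 1,
#'   `1/n_features`, 0.1).
#' @param seed RNG seed for the inner-CV fold assignment.
#' @return an object of class `regression_spec`.
#' @export
regression_spec <- function(method = c("elastic_net", "lars", "svr_rbf"),
                            inner_cv_folds = 5L, grid = list(), seed = 1L) {
  method <- match.arg(method)
  inner_cv_folds <- as.integer(inner_cv_folds)
  if (inner_cv_folds < 2L) stop("inner_cv_folds must be >= 2", call. = FALSE)
  defaults <- switch(
    method,
    lars = list(df = c(1, 2, 5, 10, 20, 50)),
    elastic_net = list(alpha = c(0.1, 0.5, 0.9), n_lambda = 20L),
    svr_rbf = list(cost = 1, gamma = NULL, epsilon = 0.1)
  )
  grid <- utils::modifyList(defaults, as.list(grid))
  structure(
    list(method = method, inner_cv_folds = inner_cv_folds, grid = grid,
         seed = as.integer(seed)),
    class = "regression_spec"
  )
}

# z-score columns by training statistics; zero-variance columns are dropped.
train_scaler <- function(train_x) {
  mu <- colMeans(train_x)
  sdev <- apply(train_x, 2L, stats::sd)
  keep <- which(sdev > 0)
  if (length(keep) < ncol(train_x)) {
    warning(sprintf("dropping %d zero-variance feature(s) on the training fold",
                    ncol(train_x) - length(keep)), call. = FALSE)
  }
  list(mu = mu[keep], sd = sdev[keep], keep = keep,
       apply = function(x) {
         sweep(sweep(x[, keep, drop = FALSE], 2L, mu[keep], "-"),
               2L, sdev[keep], "/")
       })
}

# Mean squared error of glmnet predictions per penalty value.
glmnet_cv_mse <- function(xs, ys, foldid, alpha, lambda) {
  nf <- max(foldid)
  mse <- matrix(NA_real_, nf, length(lambda))
  for (f in seq_len(nf)) {
    hold <- foldid == f
    fit <- glmnet::glmnet(xs[!hold, , drop = FALSE], ys[!hold],
                          alpha = alpha, lambda = lambda,
                          standardize = FALSE, thresh = 1e-12)
    pred <- stats::predict(fit, xs[hold, , drop = FALSE], s = lambda,
                           exact = FALSE)
    mse[f, ] <- colMeans((pred - ys[hold])^2)
  }
  colMeans(mse)
}

fit_lars <- function(xs, ys, test_xs, spec, foldid) {
  path <- glmnet::glmnet(xs, ys, alpha = 1, standardize = FALSE, thresh = 1e-12)
  targets <- unique(pmin(spec$grid$df, ncol(xs)))
  # penalty values on the path whose active-set sizes are closest to each
  # requested size; ties resolve toward the stronger penalty
  cand <- vapply(targets, function(tdf) {
    path$lambda[which.min(abs(path$df - tdf))]
  }, numeric(1))
  cand <- sort(unique(cand), decreasing = TRUE)
  if (length(cand) > 1L) {
    mse <- glmnet_cv_mse(xs, ys, foldid, alpha = 1, lambda = cand)
    best <- cand[which(mse <= min(mse) + 1e-12)]
    lam <- max(best)  # tie toward the sparser model
  } else {
    lam <- cand
  }
  drop(stats::predict(path, test_xs, s = lam, exact = FALSE))
}

fit_elastic_net <- function(xs, ys, test_xs, spec, foldid) {
  alphas <- sort(spec$grid$alpha)
  best <- list(mse = Inf, alpha = NA_real_, lambda = NA_real_, grid = NULL)
  for (alpha in alphas) {
    if (!is.null(spec$grid$lambda)) {
      lambda <- sort(unique(spec$grid$lambda), decreasing = TRUE)
    } else {
      path <- glmnet::glmnet(xs, ys, alpha = alpha, standardize = FALSE, thresh = 1e-12,
                             nlambda = spec$grid$n_lambda)
      lambda <- path$lambda
    }
    mse <- glmnet_cv_mse(xs, ys, foldid, alpha = alpha, lambda = lambda)
    cands <- which(mse <= min(mse) + 1e-12)
    lam <- max(lambda[cands])  # tie toward the stronger penalty
    m <- min(mse)
    # across alphas, ties also resolve toward the sparser (larger alpha) fit
    if (m < best$mse - 1e-12 ||
        (m <= best$mse + 1e-12 && alpha > best$alpha)) {
      best <- list(mse = m, alpha = alpha, lambda = lam, grid = lambda)
    }
  }
  fit <- glmnet::glmnet(xs, ys, alpha = best$alpha, lambda = best$grid,
                        standardize = FALSE, thresh = 1e-12)
  drop(stats::predict(fit, test_xs, s = best$lambda, exact = FALSE))
}

fit_svr <- function(xs, ys, test_xs, spec) {
  gamma <- spec$grid$gamma
  if (is.null(gamma)) gamma <- 1 / ncol(xs)
  fit <- e1071::svm(xs, ys, type = "eps-regression", kernel = "radial",
                    cost = spec$grid$cost, gamma = gamma,
                    epsilon = spec$grid$epsilon, scale = FALSE)
  drop(stats::predict(fit, test_xs))
}

#' Fit a regressor on a training fold and predict the test fold
#'
#' Features and target are z-scored using training-fold statistics only (the
#' test fold never enters fitting or normalization); predictions are returned
#' on the original target scale via the inverse training transform.
#' Zero-variance features on the training fold are dropped with a warning; a
#' zero-variance target is an error since its z-transform is undefined. If
#' every feature is dropped the prediction degenerates to the training mean.
#'
#' @param train_x,train_y training features (matrix) and target (vector).
#' @param test_x test features.
#' @param spec a [regression_spec()].
#' @return numeric vector of predictions for the test rows, original scale.
#' @export
fit_predict_partition <- function(train_x, train_y, test_x, spec) {
  if (!inherits(spec, "regression_spec")) {
    stop("`spec` must be a regression_spec()", call. = FALSE)
  }
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  train_y <- as.numeric(train_y)
  if (nrow(train_x) != length(train_y)) {
    stop("train_x and train_y disagree on the number of conditions",
         call. = FALSE)
  }
  if (ncol(train_x) != ncol(test_x)) {
    stop("train and test feature dimensions disagree", call. = FALSE)
  }
  if (nrow(train_x) < spec$inner_cv_folds) {
    stop("training fold smaller than inner_cv_folds", call. = FALSE)
  }
  my <- mean(train_y)
  sy <- stats::sd(train_y)
  if (sy == 0) {
    stop("zero-variance target on the training fold: z-scoring undefined",
         call. = FALSE)
  }
  ys <- (train_y - my) / sy
  scaler <- train_scaler(train_x)
  if (length(scaler$keep) == 0L) {
    return(stats::setNames(rep(my, nrow(test_x)), rownames(test_x)))
  }
  xs <- scaler$apply(train_x)
  test_xs <- scaler$apply(test_x)

  if (spec$method %in% c("lars", "elastic_net") && ncol(xs) < 2L) {
    # glmnet needs >= 2 columns; a single surviving feature gets a least
    # squares fit instead
    beta <- stats::lm.fit(cbind(1, xs), ys)$coefficients
    pred_s <- drop(cbind(1, test_xs) %*% beta)
  } else {
    foldid <- with_seed(spec$seed, {
      sample(rep_len(seq_len(spec$inner_cv_folds), nrow(xs)))
    })
    pred_s <- switch(
      spec$method,
      lars = fit_lars(xs, ys, test_xs, spec, foldid),
      elastic_net = fit_elastic_net(xs, ys, test_xs, spec, foldid),
      svr_rbf = fit_svr(xs, ys, test_xs, spec)
    )
  }
  stats::setNames(pred_s * sy + my, rownames(test_x))
}
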