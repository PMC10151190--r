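#' Elastic-net configuration
#'
#' Settings for the regularized regression models: the mixing-parameter grid
#' searched by nested cross-validation, the data-driven lambda path, and the
#' permutation design.
#'
#' The default alpha grid is `{0.01, 0.05, 0.10, ..., 1}`. Pure ridge
#' (`alpha = 0`) is excluded from the default because the lambda-path null
#' point is undefined there, but it may be requested explicitly. The lambda
#' path holds `n_lambda` log-spaced values from the data-derived maximum down
#' to `lambda_min_ratio` times it, recomputed on each training set.
#'
#' @param alpha_grid Ordered values in `[0, 1]`, non-empty.
#' @param n_lambda Path length.
#' @param lambda_min_ratio Smallest path value relative to lambda_max.
#' @param n_permutations Permutations for significance testing.
#' @param seed Integer seed.
#' @param thresh,maxit Coordinate-descent convergence controls.
#' @return A list of class `enet_config`.
#' @export
enet_config <- function(alpha_grid = c(0.01, seq(0.05, 1, by = 0.05)),
                        n_lambda = 100,
                        lambda_min_ratio = 0.001,
                        n_permutations = 1000,
                        seed = 1L,
                        thresh = 1e-7,
                        maxit = 100000L) {
  if (!length(alpha_grid) || any(alpha_grid < 0 | alpha_grid > 1)) {
    stop("alpha_grid must be a non-empty subset of [0, 1]", call. = FALSE)
  }
  structure(list(alpha_grid = sort(unique(alpha_grid)),
                 n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 thresh = thresh,
                 maxit = as.integer(maxit)),
            class = "enet_config")
}

# Data-driven descending lambda path. lambda_max is the smallest lambda with
# an all-zero solution at this alpha (alpha floored at 1e-3 so near-ridge
# grids still get a finite path).
lambda_path <- function(X, y, alpha, n_lambda = 100, min_ratio = 0.001) {
  Xs <- scale(X, center = TRUE, scale = FALSE)
  sds <- sqrt(colMeans(Xs^2))
  ok <- sds > 1e-14
  yc <- y - mean(y)
  lmax <- if (any(ok)) {
    max(abs(crossprod(Xs[, ok, drop = FALSE] / rep(sds[ok], each = nrow(X)), yc))) /
      nrow(X) / max(alpha, 1e-3)
  } else {
    1
  }
  lmax <- max(lmax, 1e-12)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

validate_xy <- function(X, y) {
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("non-finite values in X or y", call. = FALSE)
  }
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
}

#' Fit an elastic net at fixed hyperparameters
#'
#' Minimizes `(1/2n) sum (y - b0 - x'b)^2 + lambda * [(1-alpha)/2 sum b^2 +
#' alpha sum |b|]` with features standardized internally and coefficients
#' reported on the original scale. The solver runs coordinate descent down a
#' warm-started path ending at `lambda`.
#'
#' @param X Subjects x features matrix.
#' @param y Response vector.
#' @param alpha Mixing parameter in `[0, 1]` (1 = lasso, 0 = ridge).
#' @param lambda Penalty strength.
#' @param config An [enet_config()] (convergence controls).
#' @return A `fold_model`: list with `alpha`, `lambda`, `weights`, `intercept`.
#' @export
elastic_net_fit <- function(X, y, alpha, lambda, config = enet_config()) {
  X <- as.matrix(X)
  validate_xy(X, y)
  if (nrow(X) < 3L) stop("need at least 3 observations", call. = FALSE)
  path <- lambda_path(X, y, alpha, config$n_lambda, config$lambda_min_ratio)
  path <- c(path[path > lambda], lambda)
  fit <- cpp_enet_path(X, y, alpha, path, config$thresh, config$maxit)
  L <- length(path)
  structure(list(alpha = alpha, lambda = lambda,
                 weights = fit$beta[, L],
                 intercept = fit$intercept[L]),
            class = "fold_model")
}

#' Tune alpha and lambda by nested leave-one-out cross-validation
#'
#' For each alpha in the grid, computes the mean squared leave-one-out
#' prediction error along that alpha's lambda path (the path is fixed across
#' inner folds; each inner fold standardizes its own training rows). Returns
#' the `(alpha, lambda)` pair with minimum inner CV error; exact ties break
#' toward larger alpha, then larger lambda.
#'
#' @param X_train,y_train Training data only; the caller guarantees the
#'   held-out subject is excluded.
#' @param config An [enet_config()].
#' @return List with `alpha`, `lambda` and `cv_mse`.
#' @export
tune_alpha_nested <- function(X_train, y_train, config = enet_config()) {
  X_train <- as.matrix(X_train)
  validate_xy(X_train, y_train)
  if (!isTRUE(stats::sd(y_train) > 0)) {
    stop("degenerate target: zero variance in training set", call. = FALSE)
  }
  best <- list(alpha = NA_real_, lambda = NA_real_, cv_mse = Inf)
  for (a in config$alpha_grid) {  # ascending; ties resolve to larger alpha
    path <- lambda_path(X_train, y_train, a,
                        config$n_lambda, config$lambda_min_ratio)
    mse <- cpp_enet_cv_loo(X_train, y_train, a, path,
                           config$thresh, config$maxit)
    k <- which.min(mse)  # first minimum = largest lambda on the descending path
    if (mse[k] <= best$cv_mse) {
      best <- list(alpha = a, lambda = path[k], cv_mse = mse[k])
    }
  }
  best
}

#' Leave-one-out cross-validated elastic-net prediction
#'
#' For each outer fold: tunes `(alpha, lambda)` by nested LOOCV on the
#' training rows, refits on all training rows, and predicts the held-out
#' subject. The held-out row never enters tuning, standardization or fitting.
#'
#' @param X Subjects x features matrix.
#' @param y Target vector.
#' @param config An [enet_config()].
#' @param keep_fold_models Store per-fold weight vectors (needed by the
#'   network summaries; disable inside permutations).
#' @return A [prediction_result()] whose `fold_artifacts` holds per-fold
#'   `fold_model`s, with `alpha_per_fold` and `mean_alpha` (the model's
#'   sparsity-level summary) attached.
#' @export
loocv_enet <- function(X, y, config = enet_config(), keep_fold_models = TRUE) {
  X <- as.matrix(X)
  validate_xy(X, y)
  n <- nrow(X)
  if (n < 5L) stop("need at least 5 subjects for LOOCV", call. = FALSE)
  degenerate <- all(apply(X, 2, stats::sd) < 1e-14)
  pred <- numeric(n)
  folds <- if (keep_fold_models) vector("list", n) else NULL
  alphas <- numeric(n)
  for (i in seq_len(n)) {
    Xt <- X[-i, , drop = FALSE]
    yt <- y[-i]
    tuned <- tune_alpha_nested(Xt, yt, config)
    fm <- elastic_net_fit(Xt, yt, tuned$alpha, tuned$lambda, config)
    pred[i] <- fm$intercept + sum(fm$weights * X[i, ])
    alphas[i] <- tuned$alpha
    if (keep_fold_models) folds[[i]] <- fm
  }
  res <- prediction_result(pred, y, fold_artifacts = folds,
                           extra = list(alpha_per_fold = alphas,
                                        mean_alpha = mean(alphas),
                                        degenerate_features = degenerate))
  # constant feature matrix: intercept-only fits; accuracy is meaningless
  if (degenerate) res$accuracy_r <- NA_real_
  res
}

#' Permutation significance of an elastic-net model
#'
#' Shuffles the target and re-runs the complete nested-tuning LOOCV for every
#' permutation (hyperparameters are re-tuned per shuffle).
#'
#' @inheritParams loocv_enet
#' @return The [loocv_enet()] result with `perm_p` filled in and the null
#'   accuracy distribution attached as `null_r`.
#' @export
enet_permutation_test <- function(X, y, config = enet_config()) {
  if (config$n_permutations < 1L) stop("n_permutations must be >= 1", call. = FALSE)
  X <- as.matrix(X)
  observed <- loocv_enet(X, y, config, keep_fold_models = TRUE)
  runner <- function(target) {
    loocv_enet(X, target, config, keep_fold_models = FALSE)$accuracy_r
  }
  set.seed(config$seed)
  null_r <- vapply(seq_len(config$n_permutations), function(b) {
    r <- runner(sample(y))
    if (is.na(r)) -Inf else r
  }, numeric(1))
  observed$perm_p <- if (is.na(observed$accuracy_r)) NA_real_ else {
    (1 + sum(null_r >= observed$accuracy_r)) / (config$n_permutations + 1)
  }
  observed$null_r <- null_r
  observed
}
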