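#' Convert a test battery to percentage scores
#'
#' Each test is divided by its stated maximum and multiplied by 100; tests
#' without a stated maximum use the observed group maximum instead.
#'
#' @param battery A `battery` object (list with `scores` and `maxima`), or a
#'   subjects x tests matrix (then supply `maxima`).
#' @param maxima Optional per-test maxima (`NA` where unstated) when `battery`
#'   is a plain matrix.
#' @return A subjects x tests matrix of percentages in `[0, 100]`.
#' @export
normalize_battery <- function(battery, maxima = NULL) {
  if (inherits(battery, "battery") ||
      (is.list(battery) && !is.null(battery$scores))) {
    scores <- battery$scores
    maxima <- battery$maxima
  } else {
    scores <- battery
  }
  scores <- as.matrix(scores)
  if (any(scores < 0, na.rm = TRUE)) {
    stop("battery scores must be non-negative", call. = FALSE)
  }
  if (is.null(maxima)) maxima <- rep(NA_real_, ncol(scores))
  if (length(maxima) != ncol(scores)) {
    stop("`maxima` must have one entry per test", call. = FALSE)
  }
  eff_max <- ifelse(is.na(maxima),
                    apply(scores, 2, max, na.rm = TRUE),
                    maxima)
  if (any(eff_max <= 0)) {
    bad <- which(eff_max <= 0)
    stop(sprintf("degenerate test(s) with non-positive maximum: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  sweep(scores, 2, eff_max, `/`) * 100
}

#' Raw varimax criterion of a loading matrix
#'
#' The sum over factors of the variance of squared loadings (the quantity
#' varimax rotation maximizes), optionally after Kaiser row normalization.
#' Exposed so that rotation optimality can be checked against brute-force
#' random rotations.
#'
#' @param loadings Tests x factors loading matrix.
#' @param kaiser_normalize Divide rows by their communality square roots
#'   before evaluating (the same convention the rotation uses).
#' @return Scalar criterion value.
#' @export
varimax_criterion <- function(loadings, kaiser_normalize = TRUE) {
  L <- as.matrix(loadings)
  if (kaiser_normalize) {
    h <- sqrt(rowSums(L^2))
    h[h == 0] <- 1
    L <- L / h
  }
  p <- nrow(L)
  sq <- L^2
  sum(colSums(sq^2) - colSums(sq)^2 / p)
}

# Moore-Penrose pseudoinverse of a symmetric PSD matrix via eigendecomposition.
sym_pinv <- function(S, tol = 1e-8) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

#' Varimax-rotated principal component analysis of a test battery
#'
#' PCA on the correlation matrix of the (percentage-scaled) battery;
#' components with eigenvalue `>= 1` are retained (Kaiser rule, boundary
#' included), their loadings varimax-rotated, and regression-method projection
#' coefficients computed. Each factor is sign-flipped so that its
#' largest-magnitude loading is positive.
#'
#' @param scaled Subjects x tests matrix (output of [normalize_battery()]).
#' @param eps Varimax convergence tolerance.
#' @param kaiser_normalize Use Kaiser row normalization during rotation.
#' @return A `factor_model`: list with `loadings` (rotated, tests x retained),
#'   `eigenvalues` (all components), `coefficients` (tests x retained
#'   projection matrix), `n_retained`, `rotmat`, `center`, `scale_sd` and
#'   `dropped` (zero-variance tests removed, if any).
#' @export
fit_varimax_pca <- function(scaled, eps = 1e-10, kaiser_normalize = TRUE) {
  X <- as.matrix(scaled)
  if (ncol(X) < 2L) stop("need at least 2 tests", call. = FALSE)
  if (nrow(X) < 3L) stop("need at least 3 subjects", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  dropped <- which(sds < 1e-12)
  if (length(dropped)) {
    warning(sprintf("dropping %d zero-variance test(s): %s",
                    length(dropped),
                    paste(colnames(X)[dropped], collapse = ", ")))
    X <- X[, -dropped, drop = FALSE]
    sds <- sds[-dropped]
  }
  if (ncol(X) < 2L) stop("need at least 2 non-degenerate tests", call. = FALSE)
  ctr <- colMeans(X)
  R <- stats::cor(X)
  e <- eigen(R, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  n_ret <- sum(ev >= 1.0)
  if (n_ret == 0L) stop("no component reaches the Kaiser criterion", call. = FALSE)
  L <- e$vectors[, seq_len(n_ret), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(n_ret)]), n_ret)
  if (n_ret >= 2L) {
    vm <- stats::varimax(L, normalize = kaiser_normalize, eps = eps)
    rot <- vm$rotmat
    Lr <- L %*% rot
  } else {
    rot <- matrix(1, 1, 1)
    Lr <- L
  }
  # reproducible orientation: the dominant test of each factor loads positively
  for (f in seq_len(n_ret)) {
    j <- which.max(abs(Lr[, f]))
    if (Lr[j, f] < 0) {
      Lr[, f] <- -Lr[, f]
      rot[, f] <- -rot[, f]
    }
  }
  coef <- sym_pinv(R) %*% Lr
  rownames(Lr) <- rownames(coef) <- colnames(X)
  colnames(Lr) <- colnames(coef) <- sprintf("factor_%d", seq_len(n_ret))
  structure(list(loadings = Lr,
                 eigenvalues = ev,
                 coefficients = coef,
                 n_retained = n_ret,
                 rotmat = rot,
                 center = ctr,
                 scale_sd = sds,
                 tests = colnames(X),
                 dropped = dropped,
                 kaiser_normalize = kaiser_normalize),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> %d of %d components retained (Kaiser); eigenvalues: %s\n",
              x$n_retained, length(x$eigenvalues),
              paste(sprintf("%.2f", x$eigenvalues), collapse = ", ")))
  invisible(x)
}

#' Project factor scores
#'
#' Standardizes the battery with the fitting sample's means and standard
#' deviations, then applies the regression-method coefficient matrix. For the
#' fitting sample the scores have mean zero and unit variance per factor.
#'
#' @param model A `factor_model` from [fit_varimax_pca()].
#' @param scaled Subjects x tests percentage matrix; its tests must include
#'   the model's tests.
#' @return Subjects x retained-factors score matrix.
#' @export
project_factor_scores <- function(model, scaled) {
  X <- as.matrix(scaled)
  if (!is.null(colnames(X)) && !is.null(model$tests)) {
    if (!all(model$tests %in% colnames(X))) {
      stop("battery is missing tests the model was fitted on", call. = FALSE)
    }
    X <- X[, model$tests, drop = FALSE]
  } else if (length(model$dropped)) {
    X <- X[, -model$dropped, drop = FALSE]
  }
  if (ncol(X) != length(model$center)) {
    stop("test set does not match the model's tests", call. = FALSE)
  }
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale_sd, `/`)
  Z %*% model$coefficients
}
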