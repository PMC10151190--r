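#' Wilcoxon signed-rank test (paired differences)
#'
#' Conventions: zero differences are dropped; ties receive mid-ranks; the
#' normal-approximation z uses the tie-corrected variance and a continuity
#' correction; for n <= 25 the two-sided p comes from the exact distribution
#' of the signed-rank statistic (computed by dynamic programming over the
#' observed, possibly tied, ranks), otherwise from the normal approximation.
#' z is negative when the differences are predominantly negative in rank
#' mass.
#'
#' @param d Numeric vector of paired differences.
#' @param min_nonzero Minimum number of nonzero differences required.
#' @return List with `statistic` (W+, sum of positive ranks), `z`, `p`, `n`
#'   (nonzero pairs) and `exact` (whether the exact distribution was used).
#' @export
wilcoxon_signed_rank <- function(d, min_nonzero = 5L) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n < min_nonzero) {
    stop(sprintf("insufficient data: fewer than %d nonzero differences",
                 min_nonzero), call. = FALSE)
  }
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  sigma <- sqrt(sigma2)
  dev <- W - mu
  z <- if (dev == 0 || sigma == 0) 0 else (dev - 0.5 * sign(dev)) / sigma
  if (n <= 25L) {
    # exact null distribution over doubled ranks (integers even with midranks)
    r2 <- round(2 * rk)
    total <- sum(r2)
    f <- numeric(total + 1)
    f[1] <- 1
    for (r in r2) {
      g <- f
      g[(r + 1):(total + 1)] <- g[(r + 1):(total + 1)] + f[1:(total + 1 - r)]
      f <- g
    }
    f <- f / sum(f)
    w2 <- round(2 * W)
    supp <- 0:total
    p <- sum(f[abs(supp - 2 * mu) >= abs(w2 - 2 * mu) - 1e-9])
    exact <- TRUE
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  list(statistic = W, z = z, p = min(p, 1), n = n, exact = exact)
}

#' Compare two models' squared prediction errors
#'
#' For subjects with predictions from both models, computes
#' `d_i = (actual_i - predA_i)^2 - (actual_i - predB_i)^2` and applies the
#' Wilcoxon signed-rank test. Negative z means model B's squared errors
#' dominate in rank mass (model A's errors are smaller).
#'
#' @param pred_a,pred_b Per-subject predictions ([prediction_result()]s or
#'   numeric vectors) on aligned subjects.
#' @param actual Per-subject true scores (taken from `pred_a` when it is a
#'   [prediction_result()]).
#' @return A `comparison_result`: list with `median_sq_error` (per model),
#'   `wilcoxon_z`, `wilcoxon_p`, `n_pairs`.
#' @export
compare_squared_errors <- function(pred_a, pred_b, actual = NULL) {
  if (inherits(pred_a, "prediction_result")) {
    if (is.null(actual)) actual <- pred_a$actual
    pred_a <- pred_a$predicted
  }
  if (inherits(pred_b, "prediction_result")) pred_b <- pred_b$predicted
  if (is.null(actual)) stop("`actual` is required with plain numeric predictions", call. = FALSE)
  stopifnot(length(pred_a) == length(actual), length(pred_b) == length(actual))
  se_a <- (actual - pred_a)^2
  se_b <- (actual - pred_b)^2
  wt <- wilcoxon_signed_rank(se_a - se_b)
  structure(list(median_sq_error = c(A = stats::median(se_a),
                                     B = stats::median(se_b)),
                 wilcoxon_z = wt$z,
                 wilcoxon_p = wt$p,
                 n_pairs = wt$n,
                 exact = wt$exact),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> median sq. error A=%.3g B=%.3g | Wilcoxon z=%.3f, p=%.4g (n=%d)\n",
              x$median_sq_error[1], x$median_sq_error[2],
              x$wilcoxon_z, x$wilcoxon_p, x$n_pairs))
  invisible(x)
}

#' Residual targets from a lesion model
#'
#' The out-of-fold residuals (actual minus cross-validated prediction) of a
#' lesion model — the variance the lesion left unexplained — to be used as
#' targets for the connectivity models.
#'
#' @param lesion_result A complete [prediction_result()].
#' @return Per-subject residual vector.
#' @export
residual_targets <- function(lesion_result) {
  if (!inherits(lesion_result, "prediction_result")) {
    stop("`lesion_result` must be a prediction_result", call. = FALSE)
  }
  r <- lesion_result$residuals
  if (is.null(r) || any(is.na(r))) stop("missing predictions in lesion result", call. = FALSE)
  r
}
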