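#' Cross-validated prediction results
#'
#' Shared container for out-of-fold predictions produced by the lesion-load
#' and connectivity models: per-subject predictions, residuals, prediction
#' accuracy (Pearson r between predicted and actual), permutation p, and
#' per-fold artifacts (surviving ROI sets or weight vectors).
#'
#' @param predicted,actual Per-subject numeric vectors.
#' @param fold_artifacts Optional list of per-fold artifacts.
#' @param perm_p Optional permutation p-value.
#' @param extra Optional named list merged into the result.
#' @return An object of class `prediction_result`.
#' @export
prediction_result <- function(predicted, actual, fold_artifacts = NULL,
                              perm_p = NA_real_, extra = list()) {
  stopifnot(length(predicted) == length(actual))
  r <- if (isTRUE(stats::sd(predicted) > 0) && isTRUE(stats::sd(actual) > 0)) {
    stats::cor(predicted, actual)
  } else {
    NA_real_  # degenerate predictions: accuracy undefined, flagged as NA
  }
  structure(c(list(predicted = as.numeric(predicted),
                   actual = as.numeric(actual),
                   residuals = as.numeric(actual - predicted),
                   accuracy_r = r,
                   perm_p = perm_p,
                   fold_artifacts = fold_artifacts),
              extra),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> n=%d, accuracy r=%s, permutation p=%s\n",
              length(x$actual),
              ifelse(is.na(x$accuracy_r), "NA", sprintf("%.3f", x$accuracy_r)),
              ifelse(is.na(x$perm_p), "NA", sprintf("%.4g", x$perm_p))))
  invisible(x)
}

#' Permutation p-value for a cross-validated accuracy
#'
#' Re-runs the full modelling procedure (including ROI redefinition or
#' hyperparameter retuning) on shuffled targets and reports
#' `p = (1 + #\{null r >= observed r\}) / (n_perm + 1)`.
#'
#' @param model_runner Function taking a target vector and returning the
#'   cross-validated accuracy r for it.
#' @param target The observed target vector.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed for the shuffles.
#' @return List with `p`, `observed` and `null` (vector of null accuracies).
#' @export
permutation_pvalue <- function(model_runner, target, n_perm = 1000, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  observed <- model_runner(target)
  set.seed(as.integer(seed))
  null_r <- vapply(seq_len(n_perm), function(b) {
    r <- model_runner(sample(target))
    if (is.na(r)) -Inf else r  # degenerate null fit can never beat observed
  }, numeric(1))
  p <- if (is.na(observed)) NA_real_ else {
    (1 + sum(null_r >= observed)) / (n_perm + 1)
  }
  list(p = p, observed = observed, null = null_r)
}
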