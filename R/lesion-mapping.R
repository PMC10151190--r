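#' Lesion-mapping configuration
#'
#' Thresholds for the cross-validated voxel-based correlational analysis:
#' voxelwise FDR level, cluster-extent volume threshold (strictly greater
#' than), the cluster neighbourhood, and the permutation design.
#'
#' @param fdr_q Voxelwise false-discovery rate (Benjamini-Hochberg), in (0,1).
#' @param min_cluster_volume_mm3 Clusters must exceed this volume (strict `>`).
#' @param connectivity Cluster neighbourhood: `"face"` (default), `"edge"`,
#'   `"corner"`.
#' @param n_permutations Permutations for model significance (0 disables).
#' @param seed Integer seed for the permutation stream.
#' @return A list of class `vbcm_config`.
#' @export
vbcm_config <- function(fdr_q = 0.05,
                        min_cluster_volume_mm3 = 2000,
                        connectivity = c("face", "edge", "corner"),
                        n_permutations = 1000,
                        seed = 1L) {
  if (fdr_q <= 0 || fdr_q >= 1) stop("fdr_q must lie in (0, 1)", call. = FALSE)
  if (min_cluster_volume_mm3 <= 0) {
    stop("min_cluster_volume_mm3 must be positive", call. = FALSE)
  }
  structure(list(fdr_q = fdr_q,
                 min_cluster_volume_mm3 = min_cluster_volume_mm3,
                 connectivity = match.arg(connectivity),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "vbcm_config")
}

# Stack a list of aligned volumes into a subjects x voxels matrix.
images_to_matrix <- function(images) {
  if (is.matrix(images)) {
    dims <- attr(images, "grid_dims")
    if (is.null(dims)) stop("matrix input needs a 'grid_dims' attribute", call. = FALSE)
    voxmm <- attr(images, "voxel_mm")
    if (is.null(voxmm)) voxmm <- 2
    return(list(X = images, dims = dims, voxel_mm = voxmm))
  }
  dims <- dim(vol_data(images[[1]]))
  voxmm <- vol_voxel_mm(images[[1]])
  X <- t(vapply(images, function(im) {
    d <- vol_data(im)
    if (!identical(dim(d), dims)) stop("images are not on one grid", call. = FALSE)
    as.numeric(d)
  }, numeric(prod(dims))))
  list(X = X, dims = dims, voxel_mm = voxmm)
}

#' Voxelwise correlation map
#'
#' Pearson correlation of each voxel's value across subjects with a
#' per-subject target, with two-tailed p-values from the t transform of r on
#' n-2 degrees of freedom. Voxels with zero variance across subjects are
#' excluded (flagged, not reported as r = 0).
#'
#' @param images List of aligned [volume3d()]s (one per subject), or a
#'   subjects x voxels matrix with `grid_dims`/`voxel_mm` attributes.
#' @param target Per-subject scalar (length = number of subjects).
#' @return List with `r` and `p` ([volume3d()]s, `NA` at excluded voxels) and
#'   `excluded` (logical array).
#' @export
voxelwise_correlation <- function(images, target) {
  im <- images_to_matrix(images)
  n <- nrow(im$X)
  if (n < 4L) stop("need at least 4 subjects", call. = FALSE)
  if (length(target) != n) stop("target length must match subject count", call. = FALSE)
  cs <- vbcm_corr_stats(im$X, target,
                        colSums(im$X), colSums(im$X^2),
                        as.vector(crossprod(im$X, target)),
                        sum(target), sum(target^2), n)
  list(r = volume3d(array(cs$r, im$dims), im$voxel_mm),
       p = volume3d(array(cs$p, im$dims), im$voxel_mm),
       excluded = array(!cs$valid, im$dims))
}

# Correlation/p statistics from precomputed sums (shared by the full-sample
# map and the per-fold engine, where sums are downdated by the held-out row).
vbcm_corr_stats <- function(X, y, sx, sxx, sxy, sy, syy, n) {
  num <- n * sxy - sx * sy
  denx <- n * sxx - sx^2
  deny <- n * syy - sy^2
  valid <- denx > 1e-9 * n & deny > 1e-12
  r <- rep(NA_real_, length(sx))
  if (deny > 0) r[valid] <- num[valid] / sqrt(denx[valid] * deny)
  r <- pmax(pmin(r, 1), -1)
  df <- n - 2
  tstat <- r * sqrt(df / pmax(1 - r^2, 1e-15))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(r = r, p = p, valid = valid & !is.na(r))
}

#' Benjamini-Hochberg voxel selection
#'
#' Step-up FDR selection: with m finite p-values sorted ascending, find the
#' largest k with `p(k) <= k q / m` and select all voxels with `p <= p(k)`.
#' `NA` entries (excluded voxels) are never selected and do not count
#' towards m. An empty selection is allowed.
#'
#' @param p Numeric vector/array of p-values (`NA` allowed).
#' @param q FDR level.
#' @return Logical vector/array of selected entries.
#' @export
fdr_select <- function(p, q = 0.05) {
  pv <- as.numeric(p)
  sel <- rep(FALSE, length(pv))
  ok <- !is.na(pv)
  if (any(ok)) {
    adj <- stats::p.adjust(pv[ok], method = "BH")
    sel[ok] <- adj <= q
  }
  if (is.array(p)) sel <- array(sel, dim(p))
  sel
}

#' Extract surviving clusters from a binary map
#'
#' Labels connected components under the configured neighbourhood and drops
#' components whose volume does not exceed the cluster-extent threshold
#' (strict `>`). Surviving clusters are relabelled `1..R` by decreasing size.
#'
#' @param mask Binary [volume3d()] or logical array.
#' @param config A [vbcm_config()].
#' @param voxel_mm Voxel size when `mask` is a plain array.
#' @return A `roi_set`: list with `labels` ([volume3d()]), `sizes` (voxel
#'   counts) and `volumes_mm3`, sorted by descending size. May be empty.
#' @export
extract_clusters <- function(mask, config = vbcm_config(), voxel_mm = NULL) {
  voxmm <- if (is.null(voxel_mm)) vol_voxel_mm(mask) else voxel_mm
  labs <- label_components(vol_data(mask) != 0, config$connectivity)
  sizes <- tabulate(labs)
  keep <- which(sizes * voxmm^3 > config$min_cluster_volume_mm3)
  out <- array(0L, dim(labs))
  new_sizes <- integer(0)
  if (length(keep)) {
    relab <- integer(max(labs))
    relab[keep] <- seq_along(keep)  # labels already sorted by descending size
    inmask <- labs > 0L
    out[inmask] <- relab[labs[inmask]]
    new_sizes <- sizes[keep]
  }
  structure(list(labels = volume3d(out, voxmm),
                 sizes = new_sizes,
                 volumes_mm3 = new_sizes * voxmm^3),
            class = "roi_set")
}

#' Lesion load within ROIs
#'
#' Mean abnormality-image value within each ROI; for a binary mask this is
#' the damaged proportion of the ROI.
#'
#' @param image A [volume3d()] (continuous abnormality or binary mask).
#' @param rois A `roi_set` from [extract_clusters()], or an integer label
#'   array/volume.
#' @return Numeric vector, one mean per ROI label.
#' @export
lesion_load <- function(image, rois) {
  labs <- if (inherits(rois, "roi_set")) vol_data(rois$labels) else vol_data(rois)
  vals <- vol_data(image)
  if (!identical(dim(vals), dim(labs))) stop("image not on the ROI grid", call. = FALSE)
  K <- max(labs)
  if (K < 1L) stop("empty ROI set", call. = FALSE)
  inr <- labs > 0L
  as.numeric(rowsum(vals[inr], labs[inr])) / tabulate(labs[inr], K)
}

# Least-squares fit through the svd pseudoinverse (rank-deficiency safe).
pinv_lm <- function(A, y) {
  s <- svd(A)
  keep <- s$d > max(s$d) * 1e-10
  s$v[, keep, drop = FALSE] %*%
    ((crossprod(s$u[, keep, drop = FALSE], y)) / s$d[keep])
}

# One-target LOOCV VBCM engine over a fixed image matrix. Returns a function
# f(y, keep_artifacts) so permutations reuse all precomputed image sums.
make_vbcm_engine <- function(X, dims, voxel_mm, config) {
  n <- nrow(X)
  Sx <- colSums(X)
  Sxx <- colSums(X^2)
  force(config)
  function(y, keep_artifacts = FALSE) {
    Sxy <- as.vector(crossprod(X, y))
    Sy <- sum(y)
    Syy <- sum(y^2)
    preds <- numeric(n)
    rois <- if (keep_artifacts) vector("list", n) else NULL
    coefs <- if (keep_artifacts) vector("list", n) else NULL
    n_no_roi <- 0L
    for (i in seq_len(n)) {
      xi <- X[i, ]
      cs <- vbcm_corr_stats(X, y, Sx - xi, Sxx - xi^2, Sxy - xi * y[i],
                            Sy - y[i], Syy - y[i]^2, n - 1L)
      sel <- fdr_select(cs$p, config$fdr_q)
      train_mean <- (Sy - y[i]) / (n - 1L)
      roi <- NULL
      if (any(sel)) {
        roi <- extract_clusters(array(sel, dims), config, voxel_mm)
      }
      if (is.null(roi) || length(roi$sizes) == 0L) {
        n_no_roi <- n_no_roi + 1L
        preds[i] <- train_mean  # no surviving ROI: fall back to training mean
        if (keep_artifacts) {
          rois[[i]] <- structure(
            list(labels = volume3d(array(0L, dims), voxel_mm),
                 sizes = integer(0), volumes_mm3 = numeric(0)),
            class = "roi_set")
        }
        next
      }
      labs <- vol_data(roi$labels)
      loads <- vapply(seq_along(roi$sizes), function(k) {
        vox <- which(labs == k)
        as.numeric(X[, vox, drop = FALSE] %*% rep(1 / length(vox), length(vox)))
      }, numeric(n))
      A <- cbind(1, loads[-i, , drop = FALSE])
      beta <- pinv_lm(A, y[-i])
      preds[i] <- sum(c(1, loads[i, ]) * beta)
      if (keep_artifacts) {
        rois[[i]] <- roi
        coefs[[i]] <- beta
      }
    }
    list(predicted = preds, fold_rois = rois, fold_coefs = coefs,
         n_no_roi = n_no_roi)
  }
}

#' Leave-one-out cross-validated lesion-load model
#'
#' For each fold the training subjects alone define the voxelwise correlation
#' map, the FDR selection, the surviving clusters, and the multiple linear
#' regression of the target on per-cluster lesion loads (rank deficiency
#' resolved by the least-squares pseudoinverse); the held-out subject's loads
#' are then pushed through that model. Folds with no surviving cluster
#' predict the training-set mean. Significance comes from a permutation test
#' that re-runs the entire procedure (including ROI redefinition) per shuffle.
#'
#' @param images List of aligned continuous abnormality [volume3d()]s (or a
#'   subjects x voxels matrix with `grid_dims`/`voxel_mm` attributes).
#' @param target Per-subject behavioural score.
#' @param config A [vbcm_config()].
#' @return A [prediction_result()]; `fold_artifacts` holds each fold's
#'   `roi_set`, `extra` fields include `fold_coefs`, `n_no_roi` and (when
#'   permutations are run) `null_r`.
#' @export
loocv_lesion_model <- function(images, target, config = vbcm_config()) {
  im <- images_to_matrix(images)
  n <- nrow(im$X)
  if (n < 5L) stop("need at least 5 subjects", call. = FALSE)
  if (length(target) != n) stop("target length must match subject count", call. = FALSE)
  engine <- make_vbcm_engine(im$X, im$dims, im$voxel_mm, config)
  obs <- engine(target, keep_artifacts = TRUE)
  res <- prediction_result(obs$predicted, target,
                           fold_artifacts = obs$fold_rois,
                           extra = list(fold_coefs = obs$fold_coefs,
                                        n_no_roi = obs$n_no_roi))
  if (config$n_permutations > 0L && !is.na(res$accuracy_r)) {
    set.seed(config$seed)
    null_r <- vapply(seq_len(config$n_permutations), function(b) {
      yp <- sample(target)
      pr <- engine(yp, keep_artifacts = FALSE)$predicted
      if (isTRUE(stats::sd(pr) > 0)) stats::cor(pr, yp) else -Inf
    }, numeric(1))
    res$perm_p <- (1 + sum(null_r >= res$accuracy_r)) /
      (config$n_permutations + 1)
    res$null_r <- null_r
  }
  res
}

#' Cross-validation stability map
#'
#' Counts, per voxel, the folds in which the voxel belonged to a surviving
#' cluster. Hot voxels mark regions mapped consistently across the
#' leave-one-out loops.
#'
#' @param fold_rois List of per-fold `roi_set`s (or label volumes); `NULL`
#'   entries (folds without surviving clusters) count as empty.
#' @return A [volume3d()] of fold counts.
#' @export
stability_map <- function(fold_rois) {
  stopifnot(length(fold_rois) >= 1L)
  first <- Filter(Negate(is.null), fold_rois)
  if (!length(first)) stop("all folds are empty; no grid to map", call. = FALSE)
  proto <- if (inherits(first[[1]], "roi_set")) first[[1]]$labels else first[[1]]
  dims <- dim(vol_data(proto))
  counts <- array(0L, dims)
  for (fr in fold_rois) {
    if (is.null(fr)) next
    labs <- if (inherits(fr, "roi_set")) vol_data(fr$labels) else vol_data(fr)
    if (!identical(dim(labs), dims)) stop("fold ROI sets are not on one grid", call. = FALSE)
    counts <- counts + (labs > 0L)
  }
  volume3d(counts, vol_voxel_mm(proto))
}
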