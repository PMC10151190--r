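#' Seed-based functional connectivity map
#'
#' Correlates the mean series of a seed region (intersected with the grey
#' mask) with every in-mask voxel's series, and Fisher z-transforms the map
#' (correlations clamped to `+/-(1 - 1e-7)` first).
#'
#' @param seed_roi Binary seed [volume3d()] (e.g. a stable lesion cluster).
#' @param volume4d Subject 4D array (x, y, z, t).
#' @param grey_mask Binary analysis mask; defaults to the whole grid.
#' @return A [volume3d()] of Fisher-z values (0 outside the mask), with the
#'   analysis mask attached as attribute `mask`.
#' @export
seed_fc_map <- function(seed_roi, volume4d, grey_mask = NULL) {
  d4 <- dim(volume4d)
  dims <- d4[1:3]
  seed <- vol_data(seed_roi) != 0
  if (!identical(dim(seed), dims)) stop("seed not on the volume grid", call. = FALSE)
  grey <- if (is.null(grey_mask)) array(TRUE, dims) else vol_data(grey_mask) != 0
  seed <- seed & grey
  if (!any(seed)) stop("empty seed after grey-matter intersection", call. = FALSE)
  mat <- matrix(volume4d, prod(dims), d4[4])
  seed_series <- colMeans(mat[seed, , drop = FALSE])
  vox <- which(grey)
  r <- suppressWarnings(as.numeric(stats::cor(t(mat[vox, , drop = FALSE]),
                                              seed_series)))
  r[is.na(r)] <- 0
  z <- atanh(pmax(pmin(r, 1 - 1e-7), -(1 - 1e-7)))
  out <- array(0, dims)
  out[vox] <- z
  v <- volume3d(out, vol_voxel_mm(seed_roi))
  attr(v, "mask") <- grey
  v
}

#' Group one-sample t-map of seed connectivity
#'
#' Per-voxel one-sample t statistic of the subjects' Fisher-z values against
#' zero (df = n - 1). Voxels with zero variance across subjects are excluded
#' (NA).
#'
#' @param z_maps List of aligned [volume3d()] z maps (>= 3 subjects).
#' @param mask Optional analysis mask.
#' @return List with `t` ([volume3d()], NA at excluded voxels), `df`, `n`.
#' @export
group_tmap <- function(z_maps, mask = NULL) {
  n <- length(z_maps)
  if (n < 3L) stop("need at least 3 maps", call. = FALSE)
  dims <- dim(vol_data(z_maps[[1]]))
  X <- vapply(z_maps, function(m) {
    d <- vol_data(m)
    if (!identical(dim(d), dims)) stop("maps are not on one grid", call. = FALSE)
    as.numeric(d)
  }, numeric(prod(dims)))
  mu <- rowMeans(X)
  sdv <- sqrt(rowSums((X - mu)^2) / (n - 1))
  tv <- ifelse(sdv > 1e-12, mu / (sdv / sqrt(n)), NA_real_)
  if (!is.null(mask)) tv[!(as.vector(vol_data(mask) != 0))] <- NA_real_
  list(t = volume3d(array(tv, dims), vol_voxel_mm(z_maps[[1]])),
       df = n - 1L, n = n)
}

#' Monte-Carlo cluster-extent threshold
#'
#' Estimates the cluster size needed to control family-wise error in smooth
#' Gaussian noise: simulates `n_sims` white-noise fields, smooths them to the
#' requested FWHM, standardizes within the mask, thresholds voxels two-sided
#' at `voxel_p`, and records each field's maximum cluster size. The returned
#' threshold is the smallest integer cluster size whose exceedance
#' probability under the null is at most `cluster_p` (the ceiling of the
#' `1 - cluster_p` quantile of the max-size distribution).
#'
#' @param grid_dims Integer triple.
#' @param grey_mask Optional analysis mask (array); defaults to all voxels.
#' @param smoothness_fwhm Field smoothness FWHM in voxels (0 = independent).
#' @param voxel_p Two-sided voxel threshold.
#' @param cluster_p Target family-wise cluster error rate.
#' @param n_sims Number of null fields (>= 500).
#' @param seed Integer seed.
#' @param connectivity Cluster neighbourhood.
#' @return List with `cluster_size_thr` (voxels) and `max_sizes` (the
#'   simulated null distribution).
#' @export
montecarlo_cluster_threshold <- function(grid_dims, grey_mask = NULL,
                                         smoothness_fwhm = 2,
                                         voxel_p = 0.001, cluster_p = 0.05,
                                         n_sims = 2000, seed = 1L,
                                         connectivity = "face") {
  if (n_sims < 500) stop("need at least 500 simulations", call. = FALSE)
  if (smoothness_fwhm > min(grid_dims) / 2) {
    stop("smoothness too wide for the grid", call. = FALSE)
  }
  mask <- if (is.null(grey_mask)) array(TRUE, grid_dims) else vol_data(grey_mask) != 0
  zthr <- stats::qnorm(1 - voxel_p / 2)
  set.seed(as.integer(seed))
  max_sizes <- vapply(seq_len(n_sims), function(b) {
    max_null_cluster(grid_dims, mask, smoothness_fwhm, zthr, connectivity)
  }, numeric(1))
  thr <- smallest_fwe_threshold(max_sizes, cluster_p)
  list(cluster_size_thr = thr, max_sizes = max_sizes)
}

max_null_cluster <- function(grid_dims, mask, fwhm, zthr, connectivity) {
  field <- array(stats::rnorm(prod(grid_dims)), grid_dims)
  if (fwhm > 0) field <- gaussian_smooth3d(field, fwhm)
  v <- field[mask]
  z <- (field - mean(v)) / stats::sd(v)
  supra <- abs(z) > zthr & mask
  if (!any(supra)) return(0)
  max(tabulate(label_components(supra, connectivity)))
}

smallest_fwe_threshold <- function(max_sizes, cluster_p) {
  s <- 1L
  while (mean(max_sizes >= s) > cluster_p) s <- s + 1L
  s
}

#' Thresholded group network from seed maps
#'
#' One-sample t-test across subjects' z maps, voxel threshold at `voxel_p`
#' (two-sided), cluster-extent filter at `cluster_size_thr` voxels. By
#' default the suprathreshold mask keeps the positive tail (the networks of
#' interest are positive correlations); the negative-tail mask is also
#' returned.
#'
#' @param z_maps List of subject z maps.
#' @param voxel_p Voxel-level threshold (two-sided).
#' @param cluster_size_thr Minimum surviving cluster size (voxels), e.g. from
#'   [montecarlo_cluster_threshold()].
#' @param mask Optional analysis mask.
#' @param connectivity Cluster neighbourhood.
#' @return List with `t_map`, `mask_positive`, `mask_negative`,
#'   `cluster_size_thr`, `voxel_p`.
#' @export
group_network <- function(z_maps, voxel_p = 0.001, cluster_size_thr = 1L,
                          mask = NULL, connectivity = "face") {
  tm <- group_tmap(z_maps, mask)
  tv <- vol_data(tm$t)
  tcrit <- stats::qt(1 - voxel_p / 2, tm$df)
  keep_clusters <- function(supra) {
    labs <- label_components(supra, connectivity)
    sizes <- tabulate(labs)
    ok <- which(sizes >= cluster_size_thr)
    array(labs %in% ok & labs > 0L, dim(supra))
  }
  pos <- keep_clusters(!is.na(tv) & tv > tcrit)
  neg <- keep_clusters(!is.na(tv) & tv < -tcrit)
  list(t_map = tm$t,
       mask_positive = pos,
       mask_negative = neg,
       cluster_size_thr = cluster_size_thr,
       voxel_p = voxel_p)
}

#' Overlap of model nodes with a network mask
#'
#' A node overlaps when at least one of its atlas voxels lies inside the
#' suprathreshold network mask (default), or when its centroid voxel does
#' (`criterion = "centroid"`).
#'
#' @param top_node_ids Node (ROI) ids to score.
#' @param atlas Parcellation.
#' @param network_mask Binary suprathreshold mask (array or [volume3d()]).
#' @param criterion `"any_voxel"` (default) or `"centroid"`.
#' @return List with `count`, `k` and per-node logical `flags`.
#' @export
node_overlap <- function(top_node_ids, atlas, network_mask,
                         criterion = c("any_voxel", "centroid")) {
  criterion <- match.arg(criterion)
  a <- vol_data(atlas)
  m <- vol_data(network_mask) != 0
  if (!identical(dim(a), dim(m))) stop("atlas and mask are not aligned", call. = FALSE)
  flags <- vapply(top_node_ids, function(k) {
    if (criterion == "any_voxel") {
      any(m[a == k])
    } else {
      cen <- round(colMeans(arrayInd(which(a == k), dim(a))))
      m[cen[1], cen[2], cen[3]]
    }
  }, logical(1))
  list(count = sum(flags), k = length(top_node_ids),
       flags = stats::setNames(flags, top_node_ids))
}
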