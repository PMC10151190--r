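#' Synthetic cohort configuration
#'
#' Defines the generative conditions for a synthetic chronic-aphasia cohort:
#' grid geometry, sample sizes, parcellation size, test battery shape, the
#' variance budget linking lesions (and optionally structural connectivity)
#' to the behavioural factors, and the random seed.
#'
#' The generator emulates the structure the downstream analyses assume:
#' left-lateralized single-ellipsoid lesions (a stand-in for middle cerebral
#' artery territory strokes), a test battery linear in latent factors, ROI
#' time series with community structure attenuated at damaged ROIs, and
#' structural connectomes degraded multiplicatively by damage with an optional
#' lesion-independent signal component.
#'
#' @param grid_shape Integer triple, voxel grid dimensions. The first axis is
#'   the left-right axis; "left" means x-index `<= floor(nx/2)`.
#' @param voxel_size_mm Isotropic voxel edge length (mm).
#' @param n_patients,n_controls Cohort sizes.
#' @param n_rois Parcellation size K (must be at least 4).
#' @param n_tests,n_factors Battery shape: M tests loading on F latent factors.
#' @param n_timepoints Time series length T (at least 8).
#' @param tr_seconds Sampling interval of the simulated time series.
#' @param lesion_volume_range_mm3 Pair: admissible lesion volumes in mm^3.
#' @param effect_r2 Fraction of each factor's variance explained by lesion
#'   load in its planted critical ROI (at `noise_sd = 1`).
#' @param sc_collinear If `TRUE`, each subject's structural connectome is an
#'   exact deterministic function of the base connectome and the lesion.
#' @param sc_independent_r2 Fraction of the first factor's variance carried
#'   only by a lesion-independent structural connectivity component (ignored
#'   when `sc_collinear = TRUE`).
#' @param noise_sd Scale of the residual factor component; at the default `1`
#'   the variance budget is exact in expectation.
#' @param lesion_fwhm_vox FWHM (voxels) of the Gaussian used to produce the
#'   continuous abnormality image from the binary mask.
#' @param seed Integer seed; all generator stages derive their streams from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(grid_shape = c(24, 24, 24),
                       voxel_size_mm = 2,
                       n_patients = 60,
                       n_controls = 20,
                       n_rois = 60,
                       n_tests = 20,
                       n_factors = 4,
                       n_timepoints = 120,
                       tr_seconds = 2,
                       lesion_volume_range_mm3 = c(1000, 10000),
                       effect_r2 = 0.5,
                       sc_collinear = FALSE,
                       sc_independent_r2 = 0,
                       noise_sd = 1,
                       lesion_fwhm_vox = 2,
                       seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = voxel_size_mm,
              n_patients = as.integer(n_patients),
              n_controls = as.integer(n_controls),
              n_rois = as.integer(n_rois),
              n_tests = as.integer(n_tests),
              n_factors = as.integer(n_factors),
              n_timepoints = as.integer(n_timepoints),
              tr_seconds = tr_seconds,
              lesion_volume_range_mm3 = as.numeric(lesion_volume_range_mm3),
              effect_r2 = effect_r2,
              sc_collinear = isTRUE(sc_collinear),
              sc_independent_r2 = sc_independent_r2,
              noise_sd = noise_sd,
              lesion_fwhm_vox = lesion_fwhm_vox,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$grid_shape) == 3L, all(cfg$grid_shape >= 2L))
  if (cfg$n_rois < 4L) stop("n_rois must be >= 4", call. = FALSE)
  if (cfg$n_rois > prod(cfg$grid_shape)) {
    stop("invalid config: n_rois exceeds voxel count", call. = FALSE)
  }
  if (cfg$effect_r2 < 0 || cfg$effect_r2 > 1) {
    stop("invalid config: effect_r2 must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$sc_independent_r2 < 0 ||
      cfg$effect_r2 + cfg$sc_independent_r2 > 1) {
    stop("invalid config: effect_r2 + sc_independent_r2 must lie in [0, 1]",
         call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (cfg$n_timepoints < 8L) {
    stop("invalid config: n_timepoints must be >= 8 (correlations unstable)",
         call. = FALSE)
  }
  vr <- cfg$lesion_volume_range_mm3
  if (length(vr) != 2L || vr[1] <= 0 || vr[2] < vr[1]) {
    stop("invalid config: bad lesion_volume_range_mm3", call. = FALSE)
  }
  vox3 <- cfg$voxel_size_mm^3
  vmin_vox <- ceiling(vr[1] / vox3)
  vmax_vox <- floor(vr[2] / vox3)
  if (vmax_vox < vmin_vox || vmax_vox < 1) {
    stop("invalid config: lesion volume range infeasible at this voxel size",
         call. = FALSE)
  }
  # the largest admissible ellipsoid (at its most favourable elongation)
  # must fit inside the left half of the grid
  mid <- floor(cfg$grid_shape[1] / 2)
  r_big <- (3 * vmax_vox / (4 * pi))^(1 / 3) * 0.7
  if (2 * r_big > mid - 1 || 2 * r_big > min(cfg$grid_shape[2:3]) - 1) {
    stop("invalid config: lesion volume range infeasible on this grid",
         call. = FALSE)
  }
  invisible(cfg)
}

# Per-stage seed derivation: stage-level reproducibility without coupling.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 100000L) * 10007L + as.integer(stage)
}

grid_midline <- function(cfg) floor(cfg$grid_shape[1] / 2)

# Enumerate factor triples of K and pick the box split with the most
# cube-like blocks (deterministic; first minimum wins).
best_box_split <- function(K, dims) {
  best <- NULL
  best_score <- Inf
  for (a in seq_len(K)) {
    if (K %% a != 0) next
    rem <- K %/% a
    for (b in seq_len(rem)) {
      if (rem %% b != 0) next
      cc <- rem %/% b
      if (a > dims[1] || b > dims[2] || cc > dims[3]) next
      edges <- dims / c(a, b, cc)
      score <- max(edges) / min(edges)
      if (score < best_score - 1e-12) {
        best <- c(a, b, cc)
        best_score <- score
      }
    }
  }
  if (is.null(best)) {
    stop("invalid config: cannot partition grid into n_rois boxes", call. = FALSE)
  }
  best
}

#' Build a synthetic parcellation
#'
#' Partitions the grid into K connected, near-equal-volume box-shaped regions
#' labelled `1..K` (a desk-scale stand-in for a functional parcellation such
#' as a 200-region atlas). The partition is deterministic for a given
#' configuration.
#'
#' @param config A [sim_config()].
#' @return A [volume3d()] of integer labels `1..K`.
#' @export
make_atlas <- function(config) {
  dims <- config$grid_shape
  K <- config$n_rois
  split <- best_box_split(K, dims)
  bins <- lapply(1:3, function(ax) {
    bounds <- round(seq(0, dims[ax], length.out = split[ax] + 1L))
    findInterval(seq_len(dims[ax]) - 0.5, bounds, rightmost.closed = TRUE)
  })
  ix <- bins[[1]][slice.index(array(0L, dims), 1)]
  iy <- bins[[2]][slice.index(array(0L, dims), 2)]
  iz <- bins[[3]][slice.index(array(0L, dims), 3)]
  lab <- (ix - 1L) * split[2] * split[3] + (iy - 1L) * split[3] + iz
  volume3d(array(as.integer(lab), dims), config$voxel_size_mm)
}

roi_centroids <- function(atlas) {
  a <- vol_data(atlas)
  dims <- dim(a)
  K <- max(a)
  co <- arrayInd(seq_along(a), dims)
  t(vapply(seq_len(K), function(k) colMeans(co[a == k, , drop = FALSE]),
           numeric(3)))
}

#' Planted ground truth for a synthetic cohort
#'
#' Derives everything the generator plants and the recovery tests need:
#' critical ROIs (one per factor, all in the left half of the grid), an
#' orthogonal block test-loading matrix, a distance-decay base structural
#' connectome, lesion-independent structural signal pairs (in the never
#' lesioned right half), a spatial community assignment for the functional
#' time series, and the per-subject lesion-independent structural latent.
#'
#' @param config A [sim_config()].
#' @param atlas The parcellation from [make_atlas()].
#' @return A list of class `ground_truth`.
#' @export
make_ground_truth <- function(config, atlas) {
  a <- vol_data(atlas)
  dims <- dim(a)
  K <- config$n_rois
  F_ <- config$n_factors
  mid <- grid_midline(config)
  xcoord <- slice.index(a, 1)
  left_rois <- sort(unique(a[xcoord <= mid]))
  left_rois <- left_rois[vapply(left_rois, function(k) {
    max(xcoord[a == k]) <= mid
  }, logical(1))]
  right_rois <- setdiff(seq_len(K), sort(unique(a[xcoord <= mid])))
  if (length(left_rois) < F_) {
    stop("invalid config: fewer fully-left ROIs than factors", call. = FALSE)
  }
  critical <- left_rois[unique(round(seq(1, length(left_rois), length.out = F_)))]
  if (length(critical) < F_) critical <- left_rois[seq_len(F_)]
  critical_voxels <- lapply(critical, function(k) which(a == k))

  # orthogonal-by-construction block loading matrix (disjoint test support)
  M <- config$n_tests
  block <- pmin(F_, ceiling(seq_len(M) / (M / F_)))
  loadings <- matrix(0, M, F_)
  for (f in seq_len(F_)) {
    idx <- which(block == f)
    loadings[idx, f] <- seq(0.9, 0.65, length.out = length(idx))
  }

  cent <- roi_centroids(atlas) * config$voxel_size_mm
  d <- as.matrix(stats::dist(cent))
  base <- 0.05 + 0.75 * exp(-d / (0.3 * max(d)))
  diag(base) <- 0

  n_pairs <- min(10L, floor(length(right_rois) / 2))
  sc_signal_pairs <- if (n_pairs > 0) {
    cbind(right_rois[seq(1, 2 * n_pairs, by = 2)],
          right_rois[seq(2, 2 * n_pairs, by = 2)])
  } else {
    matrix(integer(0), 0, 2)
  }

  set.seed(stage_seed(config$seed, 1L))
  C <- max(4L, F_)
  km <- stats::kmeans(cent, centers = min(C, K), nstart = 5)
  community <- km$cluster
  sc_latent <- stats::rnorm(config$n_patients)

  structure(list(critical_roi_ids = critical,
                 critical_roi_voxels = critical_voxels,
                 factor_effect_weights = rep(1, F_),
                 test_loading_matrix = loadings,
                 sc_base_connectome = base,
                 sc_signal_pairs = sc_signal_pairs,
                 fc_community_assignment = community,
                 sc_latent = sc_latent,
                 left_rois = left_rois),
            class = "ground_truth")
}

ellipsoid_mask <- function(dims, centre, radii, x_max) {
  lo <- pmax(1L, floor(centre - radii))
  hi <- pmin(dims, ceiling(centre + radii))
  hi[1] <- min(hi[1], x_max)
  if (any(lo > hi)) return(NULL)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- ((xs - centre[1]) / radii[1])^2
  dy2 <- ((ys - centre[2]) / radii[2])^2
  dz2 <- ((zs - centre[3]) / radii[3])^2
  inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
  list(lo = lo, hi = hi, inside = inside)
}

#' Simulate left-hemisphere lesions
#'
#' Each patient receives a single ellipsoidal lesion confined to the left half
#' of the grid (x-index `<= floor(nx/2)`), with volume drawn uniformly from
#' the configured range. The continuous abnormality image is the binary mask
#' smoothed with a Gaussian kernel (`lesion_fwhm_vox`), with values in [0, 1].
#'
#' @param config A [sim_config()].
#' @return A list with one element per patient, each a list with `mask`
#'   (logical [volume3d()]) and `abnormality` (numeric [volume3d()]).
#' @export
simulate_lesions <- function(config) {
  validate_sim_config(config)
  dims <- config$grid_shape
  mid <- grid_midline(config)
  vox3 <- config$voxel_size_mm^3
  vmin_vox <- ceiling(config$lesion_volume_range_mm3[1] / vox3)
  vmax_vox <- floor(config$lesion_volume_range_mm3[2] / vox3)
  set.seed(stage_seed(config$seed, 2L))
  out <- vector("list", config$n_patients)
  for (s in seq_len(config$n_patients)) {
    n_target <- stats::runif(1, vmin_vox, vmax_vox)
    q <- stats::runif(3, 0.7, 1.4)
    q <- q / prod(q)^(1 / 3)
    r <- (3 * n_target / (4 * pi))^(1 / 3) * q
    centre <- c(
      stats::runif(1, min(1 + r[1], mid / 2), max(mid - r[1], mid / 2)),
      stats::runif(1, min(1 + r[2], dims[2] / 2), max(dims[2] - r[2], dims[2] / 2)),
      stats::runif(1, min(1 + r[3], dims[3] / 2), max(dims[3] - r[3], dims[3] / 2))
    )
    scale <- 1
    mask <- array(FALSE, dims)
    for (it in 1:40) {
      em <- ellipsoid_mask(dims, centre, r * scale, mid)
      cnt <- if (is.null(em)) 0L else sum(em$inside)
      if (cnt < vmin_vox) {
        scale <- scale * 1.08
      } else if (cnt > vmax_vox) {
        scale <- scale * 0.94
      } else break
    }
    em <- ellipsoid_mask(dims, centre, r * scale, mid)
    if (is.null(em) || sum(em$inside) < vmin_vox || sum(em$inside) > vmax_vox) {
      stop("lesion generation failed to satisfy the volume range", call. = FALSE)
    }
    mask[em$lo[1]:em$hi[1], em$lo[2]:em$hi[2], em$lo[3]:em$hi[3]] <- em$inside
    abn <- gaussian_smooth3d(mask * 1, config$lesion_fwhm_vox)
    abn <- pmin(pmax(abn, 0), 1)  # FFT roundoff can leave ~1e-17 negatives
    out[[s]] <- list(mask = volume3d(mask, config$voxel_size_mm),
                     abnormality = volume3d(abn, config$voxel_size_mm))
  }
  out
}

# Damaged fraction of every ROI for one binary lesion mask.
roi_damage_fraction <- function(mask, atlas) {
  a <- vol_data(atlas)
  K <- max(a)
  sizes <- tabulate(a, K)
  hit <- tabulate(a[vol_data(mask) != 0], K)
  hit / sizes
}

#' Simulate behavioural battery scores
#'
#' Each latent factor is `sqrt(effect_r2) * z(1 - lesion load in its critical
#' ROI) + [for the first factor] sqrt(sc_independent_r2) * z(SC latent) +
#' noise_sd * sqrt(1 - effect_r2 - sc_independent_r2) * N(0,1)`. Test scores
#' are a linear image of the factors through the planted orthogonal loading
#' matrix plus test noise, clipped to `[0, max]`. A quarter of tests carry no
#' stated maximum, exercising the group-maximum normalization path.
#'
#' @param config A [sim_config()].
#' @param lesions Output of [simulate_lesions()].
#' @param truth Output of [make_ground_truth()].
#' @return A `battery` object (list with `scores`: patients x tests matrix,
#'   and `maxima`: per-test maximum, `NA` where unstated) with attribute
#'   `latent_factors` (patients x factors matrix of the planted factors).
#' @export
simulate_cohort_behaviour <- function(config, lesions, truth) {
  validate_sim_config(config)
  n <- length(lesions)
  F_ <- config$n_factors
  e <- config$effect_r2
  s <- if (config$sc_collinear) 0 else config$sc_independent_r2
  set.seed(stage_seed(config$seed, 3L))
  factors <- matrix(0, n, F_)
  if (n == 0L) {
    M <- config$n_tests
    scores <- matrix(numeric(0), 0, M,
                     dimnames = list(NULL, sprintf("test_%02d", seq_len(M))))
    maxima <- stats::setNames(rep(100, M), colnames(scores))
    return(structure(list(scores = scores, maxima = maxima),
                     class = "battery", latent_factors = factors))
  }
  for (f in seq_len(F_)) {
    intact <- vapply(lesions, function(l) {
      1 - mean(vol_data(l$mask)[truth$critical_roi_voxels[[f]]])
    }, numeric(1))
    zL <- if (isTRUE(stats::sd(intact) > 0)) as.numeric(scale(intact)) else rep(0, n)
    resid_share <- 1 - e - if (f == 1L) s else 0
    fac <- sqrt(e) * zL +
      config$noise_sd * sqrt(max(resid_share, 0)) * stats::rnorm(n)
    if (f == 1L && s > 0) {
      g <- truth$sc_latent[seq_len(n)]
      zG <- if (isTRUE(stats::sd(g) > 0)) as.numeric(scale(g)) else rep(0, n)
      fac <- fac + sqrt(s) * zG
    }
    factors[, f] <- fac
  }
  M <- config$n_tests
  maxima <- rep(100, M)
  maxima[seq_len(M) %% 4L == 0L] <- NA
  raw <- 60 + 12 * factors %*% t(truth$test_loading_matrix) +
    matrix(stats::rnorm(n * M, sd = 5), n, M)
  raw <- pmin(pmax(raw, 0), 100)
  colnames(raw) <- sprintf("test_%02d", seq_len(M))
  names(maxima) <- colnames(raw)
  structure(list(scores = raw, maxima = maxima),
            class = "battery", latent_factors = factors)
}

# Community-structured ROI time series for one subject.
roi_series_one <- function(K, T_, community, damage, within_share = 0.85) {
  C <- max(community)
  Z <- matrix(stats::rnorm(C * T_), C, T_)
  w <- within_share * (1 - damage)
  w * Z[community, , drop = FALSE] +
    sqrt(1 - w^2) * matrix(stats::rnorm(K * T_), K, T_)
}

#' Simulate ROI time series for patients and controls
#'
#' Every ROI's signal is a mixture of its community's latent series and
#' idiosyncratic noise; the latent share is `0.85 * (1 - damaged fraction)`,
#' so a fully damaged ROI carries pure noise. Controls use zero damage.
#'
#' @param config A [sim_config()].
#' @param lesions Output of [simulate_lesions()].
#' @param atlas The parcellation.
#' @param truth Ground truth (provides the community assignment).
#' @param within_share Latent community-signal share of an undamaged ROI's
#'   variance mixture (default 0.85).
#' @return List with `patients` and `controls`, each a list of K x T matrices.
#' @export
simulate_timeseries <- function(config, lesions, atlas, truth,
                                within_share = 0.85) {
  validate_sim_config(config)
  K <- config$n_rois
  T_ <- config$n_timepoints
  comm <- truth$fc_community_assignment
  set.seed(stage_seed(config$seed, 4L))
  patients <- lapply(lesions, function(l) {
    roi_series_one(K, T_, comm, roi_damage_fraction(l$mask, atlas),
                   within_share)
  })
  controls <- lapply(seq_len(config$n_controls), function(i) {
    roi_series_one(K, T_, comm, rep(0, K), within_share)
  })
  list(patients = patients, controls = controls)
}

#' Simulate a control resting-state 4D volume
#'
#' Voxel series share their ROI's community latent signal (share 0.85) plus
#' voxel noise; used by the healthy seed-network stage.
#'
#' @param config,atlas,truth As elsewhere in the generator.
#' @param control_id Integer id of the control subject (enters the seed).
#' @return A 4D array (x, y, z, t).
#' @export
simulate_control_volume <- function(config, atlas, truth, control_id = 1L) {
  a <- vol_data(atlas)
  dims <- dim(a)
  T_ <- config$n_timepoints
  comm <- truth$fc_community_assignment
  C <- max(comm)
  set.seed(stage_seed(config$seed, 100L + as.integer(control_id)))
  Z <- matrix(stats::rnorm(C * T_), C, T_)
  w <- 0.85
  vox_comm <- comm[as.vector(a)]
  mat <- w * Z[vox_comm, , drop = FALSE] +
    sqrt(1 - w^2) * matrix(stats::rnorm(length(a) * T_), length(a), T_)
  array(mat, c(dims, T_))
}

#' Simulate structural connectomes
#'
#' With `sc_collinear = TRUE` the subject connectome is exactly
#' `base[i, j] * (1 - damage_i) * (1 - damage_j)` — a deterministic function
#' of the lesion, operationalizing lesion/disconnection collinearity.
#' Otherwise, when `sc_independent_r2 > 0`, designated right-hemisphere ROI
#' pairs additionally carry a subject-specific latent (`truth$sc_latent`)
#' that is independent of the lesion and tied to the first factor.
#'
#' @param config,lesions,atlas,truth As elsewhere in the generator.
#' @return A list of K x K symmetric matrices with entries in `[0, 1]`.
#' @export
simulate_structural_connectomes <- function(config, lesions, atlas, truth) {
  validate_sim_config(config)
  base <- truth$sc_base_connectome
  lapply(seq_along(lesions), function(s) {
    d <- roi_damage_fraction(lesions[[s]]$mask, atlas)
    S <- base * outer(1 - d, 1 - d)
    if (!config$sc_collinear && config$sc_independent_r2 > 0 &&
        nrow(truth$sc_signal_pairs) > 0) {
      g <- truth$sc_latent[s]
      for (p in seq_len(nrow(truth$sc_signal_pairs))) {
        i <- truth$sc_signal_pairs[p, 1]
        j <- truth$sc_signal_pairs[p, 2]
        v <- min(max(base[i, j] + 0.15 * g, 0), 1)
        S[i, j] <- v
        S[j, i] <- v
      }
    }
    diag(S) <- 0
    S
  })
}

#' Generate a complete synthetic cohort
#'
#' Runs the whole generator (atlas, ground truth, lesions, behaviour, time
#' series, structural connectomes) from one configuration. Identical
#' configurations (including the seed) reproduce the cohort bitwise.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_cohort` with elements `config`, `atlas`,
#'   `truth` (including `latent_factors`), `lesions`, `battery`, `timeseries`
#'   and `sc`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  atlas <- make_atlas(config)
  truth <- make_ground_truth(config, atlas)
  lesions <- simulate_lesions(config)
  battery <- simulate_cohort_behaviour(config, lesions, truth)
  truth$latent_factors <- attr(battery, "latent_factors")
  ts <- simulate_timeseries(config, lesions, atlas, truth)
  sc <- simulate_structural_connectomes(config, lesions, atlas, truth)
  structure(list(config = config, atlas = atlas, truth = truth,
                 lesions = lesions, battery = battery,
                 timeseries = ts, sc = sc),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d patients, %d controls | grid %s @ %g mm | K=%d, M=%d, F=%d, T=%d\n",
    x$config$n_patients, x$config$n_controls,
    paste(x$config$grid_shape, collapse = "x"), x$config$voxel_size_mm,
    x$config$n_rois, x$config$n_tests, x$config$n_factors,
    x$config$n_timepoints))
  invisible(x)
}
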