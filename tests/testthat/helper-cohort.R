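# Small cohort factories shared across tests.

tiny_config <- function(seed = 1, ...) {
  defaults <- list(grid_shape = c(12, 12, 12), voxel_size_mm = 2,
                   n_patients = 20, n_controls = 3, n_rois = 8,
                   n_tests = 12, n_factors = 4, n_timepoints = 40,
                   lesion_volume_range_mm3 = c(150, 900),
                   effect_r2 = 0.5, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Geometry used for parameter-recovery runs: K=16 on a 16^3 grid gives
# 256-voxel (2048 mm^3) planted ROIs, lesions span 25..200 voxels.
recovery_config <- function(seed = 1, ...) {
  defaults <- list(grid_shape = c(16, 16, 16), voxel_size_mm = 2,
                   n_patients = 60, n_controls = 2, n_rois = 16,
                   n_tests = 12, n_factors = 4, n_timepoints = 40,
                   lesion_volume_range_mm3 = c(200, 1600),
                   effect_r2 = 0.5, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Factor score (from the battery pipeline) best matching planted factor 1,
# oriented so higher score = more intact tissue.
matched_factor_score <- function(cohort, planted = 1L) {
  scaled <- normalize_battery(cohort$battery)
  fm <- fit_varimax_pca(scaled)
  scores <- project_factor_scores(fm, scaled)
  cc <- stats::cor(scores, cohort$truth$latent_factors[, planted])
  j <- which.max(abs(cc))
  scores[, j] * sign(cc[j])
}

empty_lesion <- function(config) {
  list(mask = volume3d(array(FALSE, config$grid_shape), config$voxel_size_mm))
}
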