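test_that("atlas partitions the grid into connected, near-equal regions", {
  cfg <- tiny_config(grid_shape = c(4, 4, 4), n_rois = 8,
                     lesion_volume_range_mm3 = c(8, 8))
  atlas <- make_atlas(cfg)
  expect_equal(sort(unique(as.vector(atlas$data))), 1:8)
  expect_true(all(tabulate(atlas$data) == 8L))  # 8 blocks of 8 voxels
  expect_identical(make_atlas(cfg)$data, atlas$data)  # deterministic

  cfg2 <- tiny_config(grid_shape = c(8, 8, 8), n_rois = 64,
                      lesion_volume_range_mm3 = c(16, 120))
  a2 <- make_atlas(cfg2)$data
  for (k in sample(64, 8)) {
    comp <- label_components(a2 == k, "face")
    expect_equal(max(comp), 1L)  # each region face-connected
  }
  sizes <- tabulate(a2, 64)
  expect_true(max(sizes) <= 2 * min(sizes))
})

test_that("infeasible configurations are rejected", {
  expect_error(tiny_config(n_rois = 3), "n_rois")
  expect_error(sim_config(grid_shape = c(2, 2, 2), n_rois = 9), "voxel count")
  expect_error(tiny_config(effect_r2 = 1.2), "effect_r2")
  expect_error(tiny_config(effect_r2 = 0.8, sc_independent_r2 = 0.5), "sc_independent_r2")
  expect_error(tiny_config(n_timepoints = 4), "n_timepoints")
  expect_error(tiny_config(lesion_volume_range_mm3 = c(1, 2)), "infeasible")
  expect_error(tiny_config(lesion_volume_range_mm3 = c(100, 1e6)), "infeasible")
})

test_that("lesions respect laterality and the volume range", {
  cfg <- sim_config(grid_shape = c(16, 16, 16), voxel_size_mm = 2,
                    n_patients = 100, n_rois = 8, n_tests = 8,
                    lesion_volume_range_mm3 = c(80, 400), seed = 5)
  les <- simulate_lesions(cfg)
  counts <- vapply(les, function(l) sum(l$mask$data), numeric(1))
  expect_true(all(counts >= 10 & counts <= 50))  # 80..400 mm^3 at 8 mm^3/voxel
  mid <- floor(16 / 2)
  maxx <- vapply(les, function(l) max(which(apply(l$mask$data, 1, any))), numeric(1))
  expect_true(all(maxx <= mid))
  for (l in les[1:5]) {
    expect_equal(max(label_components(l$mask$data)), 1L)  # single component
    expect_true(all(l$abnormality$data >= 0 & l$abnormality$data <= 1))
  }
  expect_length(simulate_lesions(tiny_config(n_patients = 0)), 0L)
})

test_that("behaviour honours the variance budget", {
  cfg <- sim_config(grid_shape = c(12, 12, 12), n_patients = 500,
                    n_controls = 0, n_rois = 8, n_tests = 8, n_factors = 2,
                    n_timepoints = 8, lesion_volume_range_mm3 = c(100, 800),
                    effect_r2 = 0.5, seed = 11)
  atlas <- make_atlas(cfg)
  truth <- make_ground_truth(cfg, atlas)
  les <- simulate_lesions(cfg)
  bat <- simulate_cohort_behaviour(cfg, les, truth)
  f <- attr(bat, "latent_factors")
  load1 <- vapply(les, function(l) mean(l$mask$data[truth$critical_roi_voxels[[1]]]),
                  numeric(1))
  expect_equal(cor(f[, 1], load1)^2, 0.5, tolerance = 0.1)

  cfg0 <- sim_config(grid_shape = c(12, 12, 12), n_patients = 200,
                     n_controls = 0, n_rois = 8, n_tests = 8, n_factors = 2,
                     n_timepoints = 8, lesion_volume_range_mm3 = c(100, 800),
                     effect_r2 = 0, seed = 12)
  les0 <- simulate_lesions(cfg0)
  bat0 <- simulate_cohort_behaviour(cfg0, les0, make_ground_truth(cfg0, atlas))
  f0 <- attr(bat0, "latent_factors")
  load0 <- vapply(les0, function(l) mean(l$mask$data[truth$critical_roi_voxels[[1]]]),
                  numeric(1))
  expect_lt(abs(cor(f0[, 1], load0)), 0.15)
})

test_that("noise-free behaviour is an exact affine function of lesion load", {
  cfg <- tiny_config(effect_r2 = 1, noise_sd = 0, n_factors = 2, n_patients = 15)
  atlas <- make_atlas(cfg)
  truth <- make_ground_truth(cfg, atlas)
  les <- simulate_lesions(cfg)
  f <- attr(simulate_cohort_behaviour(cfg, les, truth), "latent_factors")
  load1 <- vapply(les, function(l) mean(l$mask$data[truth$critical_roi_voxels[[1]]]),
                  numeric(1))
  expect_equal(abs(cor(f[, 1], load1)), 1, tolerance = 1e-12)
  # identical lesions, zero noise: identical factor scores
  les_dup <- les
  les_dup[[2]] <- les_dup[[1]]
  f2 <- attr(simulate_cohort_behaviour(cfg, les_dup, truth), "latent_factors")
  expect_equal(f2[1, ], f2[2, ])
})

test_that("time series express community structure degraded by damage", {
  cfg <- tiny_config(n_patients = 1, n_timepoints = 200, n_rois = 8)
  atlas <- make_atlas(cfg)
  truth <- make_ground_truth(cfg, atlas)
  # near-deterministic latent share: same-community ROIs correlate ~1
  ts <- simulate_timeseries(cfg, list(empty_lesion(cfg)), atlas, truth,
                            within_share = 1 - 1e-9)
  comm <- truth$fc_community_assignment
  pair <- which(comm == comm[which.max(tabulate(comm))])[1:2]
  expect_gt(cor(ts$patients[[1]][pair[1], ], ts$patients[[1]][pair[2], ]), 0.99)

  # different-community ROIs: mean correlation near zero over 50 draws
  pairs_between <- which(outer(comm, comm, `!=`) & upper.tri(diag(8)),
                         arr.ind = TRUE)[1, ]
  rs <- vapply(1:50, function(i) {
    cfg_i <- tiny_config(seed = 100 + i, n_patients = 1, n_timepoints = 100)
    tsi <- simulate_timeseries(cfg_i, list(empty_lesion(cfg_i)), atlas, truth)
    cor(tsi$patients[[1]][pairs_between[1], ], tsi$patients[[1]][pairs_between[2], ])
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)

  # a fully damaged ROI is pure noise
  roi1 <- truth$critical_roi_ids[1]
  full <- list(mask = volume3d(array(atlas$data == roi1, cfg$grid_shape),
                               cfg$voxel_size_mm))
  rs_lesioned <- vapply(1:50, function(i) {
    cfg_i <- tiny_config(seed = 200 + i, n_patients = 1, n_timepoints = 100)
    tsi <- simulate_timeseries(cfg_i, list(full), atlas, truth)
    mean(abs(cor(t(tsi$patients[[1]]))[roi1, -roi1]))
  }, numeric(1))
  expect_lt(mean(rs_lesioned), 0.1)
})

test_that("structural connectomes degrade deterministically with damage", {
  cfg <- tiny_config(sc_collinear = TRUE, n_patients = 2)
  atlas <- make_atlas(cfg)
  truth <- make_ground_truth(cfg, atlas)
  # no lesion: subject connectome equals the base connectome
  sc0 <- simulate_structural_connectomes(cfg, list(empty_lesion(cfg)), atlas, truth)
  expect_equal(sc0[[1]], truth$sc_base_connectome)
  # a 100% damaged ROI zeroes its row and column
  roi1 <- truth$critical_roi_ids[1]
  full <- list(mask = volume3d(array(atlas$data == roi1, cfg$grid_shape),
                               cfg$voxel_size_mm))
  sc1 <- simulate_structural_connectomes(cfg, list(full), atlas, truth)
  expect_true(all(sc1[[1]][roi1, ] == 0) && all(sc1[[1]][, roi1] == 0))
  # deterministic function of (base, lesion): regenerate and compare
  les <- simulate_lesions(cfg)
  a <- simulate_structural_connectomes(cfg, les, atlas, truth)
  b <- simulate_structural_connectomes(cfg, les, atlas, truth)
  expect_identical(a, b)
  for (S in a) {
    expect_true(isSymmetric(S))
    expect_true(all(S >= 0 & S <= 1))
  }
})

test_that("identical configurations reproduce the cohort bitwise", {
  co1 <- simulate_cohort(tiny_config(seed = 33))
  co2 <- simulate_cohort(tiny_config(seed = 33))
  expect_identical(co1$lesions, co2$lesions)
  expect_identical(co1$battery, co2$battery)
  expect_identical(co1$timeseries, co2$timeseries)
  expect_identical(co1$sc, co2$sc)
  co3 <- simulate_cohort(tiny_config(seed = 34))
  expect_false(identical(co1$battery, co3$battery))
})

test_that("critical ROIs lie fully in the left half and loadings are orthogonal", {
  cfg <- tiny_config()
  atlas <- make_atlas(cfg)
  truth <- make_ground_truth(cfg, atlas)
  mid <- floor(cfg$grid_shape[1] / 2)
  xcoord <- slice.index(atlas$data, 1)
  for (k in truth$critical_roi_ids) {
    expect_lte(max(xcoord[atlas$data == k]), mid)
  }
  G <- crossprod(truth$test_loading_matrix)
  expect_equal(G - diag(diag(G)), matrix(0, ncol(G), ncol(G)))
})
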