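test_that("detrending and ideal bandpass behave spectrally as expected", {
  T_ <- 120; tr <- 2
  tt <- seq_len(T_)
  ramp <- matrix(5 * tt, 1)
  out <- detrend_bandpass(ramp, tr)
  expect_lt(max(abs(out)), 1e-6 * max(ramp))
  # 0.05 Hz lies in band (0.01-0.08): amplitude preserved within 10%
  s_in <- matrix(sin(2 * pi * 0.05 * tt * tr), 1)
  out_in <- detrend_bandpass(s_in, tr)
  expect_equal(max(abs(out_in)), 1, tolerance = 0.1)
  # 0.2 Hz is out of band: attenuated by > 90%
  s_out <- matrix(sin(2 * pi * 0.2 * tt * tr), 1)
  expect_lt(max(abs(detrend_bandpass(s_out, tr))), 0.1)
  expect_error(detrend_bandpass(matrix(rnorm(10), 1), tr), "16")
  expect_error(detrend_bandpass(matrix(rnorm(2 * T_), 2), tr, 0.1, 0.4), "Nyquist")
})

test_that("ROI time courses are within-region voxel means", {
  dims <- c(4, 4, 2)
  atlas <- array(1L, dims)
  atlas[3:4, , ] <- 2L
  atlas[1, 1, 1] <- 3L
  T_ <- 5
  v4 <- array(2, c(dims, T_))
  ts <- roi_timeseries(v4, volume3d(atlas, 2))
  expect_true(all(ts == 2))
  # single-voxel ROI equals that voxel's series
  v4b <- array(rnorm(prod(dims) * T_), c(dims, T_))
  tsb <- roi_timeseries(v4b, volume3d(atlas, 2))
  expect_equal(tsb[3, ], v4b[1, 1, 1, ])
  # two-value checkerboard averages to the midpoint
  v4c <- array(0, c(dims, T_))
  idx2 <- which(atlas == 2L)
  half <- idx2[seq(1, length(idx2), by = 2)]
  for (t in seq_len(T_)) {
    vol <- array(0, dims)
    vol[half] <- 4
    v4c[, , , t] <- vol
  }
  expect_equal(roi_timeseries(v4c, volume3d(atlas, 2))[2, ], rep(2, T_))
})

test_that("FC matrices are clamped Fisher-z with degenerate rows masked", {
  set.seed(1)
  x <- rnorm(50)
  y <- rnorm(50)
  s <- rbind(x, x + 0 * y, y)   # rows 1 and 2 identical
  z <- fc_matrix(s)
  expect_equal(z[1, 2], atanh(1 - 1e-7))  # clamped, finite
  expect_equal(z[1, 3], atanh(cor(x, y)), tolerance = 1e-12)
  expect_true(all(is.finite(z)))
  expect_equal(diag(z), rep(0, 3), ignore_attr = TRUE)
  s2 <- rbind(x, rep(3, 50), y)  # constant row
  z2 <- fc_matrix(s2)
  expect_equal(attr(z2, "masked_rois"), 2L)
  expect_true(all(z2[2, ] == 0))
})

test_that("lesion masking of FC zeroes any overlapping ROI, however small", {
  cfg <- tiny_config(n_timepoints = 30)
  atlas <- make_atlas(cfg)
  set.seed(2)
  s <- matrix(rnorm(8 * 30), 8, 30)
  z <- fc_matrix(s)
  no_lesion <- volume3d(array(FALSE, cfg$grid_shape), 2)
  expect_equal(lesion_mask_fc(z, no_lesion, atlas), z, ignore_attr = TRUE)
  one_vox <- array(FALSE, cfg$grid_shape)
  one_vox[which(atlas$data == 3L)[1]] <- TRUE
  zm <- lesion_mask_fc(z, volume3d(one_vox, 2), atlas)
  expect_true(all(zm[3, ] == 0) && all(zm[, 3] == 0))
  expect_equal(zm[-3, -3], z[-3, -3], ignore_attr = TRUE)
  expect_true(3L %in% attr(zm, "masked_rois"))
  all_vox <- volume3d(array(TRUE, cfg$grid_shape), 2)
  expect_true(all(lesion_mask_fc(z, all_vox, atlas) == 0))
})

test_that("SC symmetrization averages reciprocals and masks >95% damage", {
  raw <- matrix(0, 3, 3)
  raw[1, 2] <- 0.2; raw[2, 1] <- 0.4
  s <- symmetrize_and_mask_sc(raw)
  expect_equal(s[1, 2], 0.3)
  expect_equal(s[2, 1], 0.3)
  expect_error(symmetrize_and_mask_sc(matrix(-1, 2, 2)), "non-negative")
  sym <- matrix(c(0, .5, .5, 0), 2)
  expect_equal(symmetrize_and_mask_sc(sym), sym, ignore_attr = TRUE)

  # 25-voxel ROIs: 24/25 = 96% damaged -> masked; 19/20... use exact 95%
  dims <- c(10, 5, 1)
  atlas <- array(2L, dims)
  atlas[1:5, , 1] <- 1L   # ROI 1: 25 voxels
  lesion <- array(FALSE, dims)
  lesion[which(atlas == 1L)[1:24]] <- TRUE  # 96% of ROI 1
  K2 <- matrix(0.4, 2, 2); diag(K2) <- 0
  s96 <- symmetrize_and_mask_sc(K2, volume3d(lesion, 2), volume3d(atlas, 2))
  expect_true(all(s96[1, ] == 0))
  lesion95 <- array(FALSE, dims)
  # ROI 2 has 25 voxels; damage 19 of 20? construct exact 95%: 19/20 needs 20 voxels
  atlas20 <- array(2L, c(8, 5, 1))
  atlas20[1:4, , 1] <- 1L  # ROI 1: 20 voxels
  l19 <- array(FALSE, c(8, 5, 1))
  l19[which(atlas20 == 1L)[1:19]] <- TRUE  # exactly 95%: kept (strict >)
  s95 <- symmetrize_and_mask_sc(K2, volume3d(l19, 2), volume3d(atlas20, 2))
  expect_equal(s95[1, 2], 0.4)
})

test_that("lower-triangle vectorization uses the fixed column-major order", {
  m <- matrix(0, 3, 3)
  m[2, 1] <- m[1, 2] <- 21
  m[3, 1] <- m[1, 3] <- 31
  m[3, 2] <- m[2, 3] <- 32
  expect_equal(vectorize_lower(m), c(21, 31, 32))
  pm <- pair_index_map(3)
  expect_equal(pm$i, c(2, 3, 3))
  expect_equal(pm$j, c(1, 1, 2))
  # K = 200 parcellation -> 19,900 features
  big <- matrix(0, 200, 200)
  expect_length(vectorize_lower(big), 19900L)
  # round trip
  set.seed(3)
  sym <- matrix(rnorm(25), 5)
  sym <- sym + t(sym); diag(sym) <- 0
  expect_equal(unvectorize_lower(vectorize_lower(sym), 5), sym)
  asym <- sym; asym[1, 2] <- 99
  expect_error(vectorize_lower(asym), "symmetric")
})

test_that("masking commutes with vectorization", {
  cfg <- tiny_config(n_timepoints = 30)
  atlas <- make_atlas(cfg)
  set.seed(4)
  z <- fc_matrix(matrix(rnorm(8 * 30), 8, 30))
  lesion <- array(FALSE, cfg$grid_shape)
  lesion[atlas$data == 2L] <- TRUE
  lesion_vol <- volume3d(lesion, 2)
  v1 <- vectorize_lower(lesion_mask_fc(z, lesion_vol, atlas))
  pm <- pair_index_map(8)
  v2 <- vectorize_lower(z)
  hit <- 2L
  v2[pm$i == hit | pm$j == hit] <- 0
  expect_equal(v1, v2)
})

test_that("healthy subjects show within- over between-community connectivity", {
  cfg <- tiny_config(n_timepoints = 100, n_rois = 12)
  atlas <- make_atlas(cfg)
  truth <- make_ground_truth(cfg, atlas)
  comm <- truth$fc_community_assignment
  within <- outer(comm, comm, `==`) & lower.tri(diag(12))
  between <- outer(comm, comm, `!=`) & lower.tri(diag(12))
  ok <- vapply(1:40, function(i) {
    cfg_i <- tiny_config(seed = 300 + i, n_timepoints = 100, n_rois = 12,
                         n_patients = 1)
    ts <- simulate_timeseries(cfg_i, list(empty_lesion(cfg_i)), atlas, truth)
    z <- fc_matrix(ts$patients[[1]])
    mean(z[within]) > mean(z[between])
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("cohort feature matrices have the documented shape and order", {
  co <- simulate_cohort(tiny_config(n_patients = 6, n_timepoints = 40))
  Xfc <- cohort_features(co, "FC", bandpass = TRUE)
  Xsc <- cohort_features(co, "SC")
  Xboth <- cohort_features(co, "FCSC", bandpass = TRUE)
  P <- 8 * 7 / 2
  expect_equal(dim(Xfc), c(6, P))
  expect_equal(dim(Xsc), c(6, P))
  expect_equal(dim(Xboth), c(6, 2 * P))
  expect_equal(Xboth[, seq_len(P)], Xfc, ignore_attr = TRUE)
  expect_equal(Xboth[, P + seq_len(P)], Xsc, ignore_attr = TRUE)
})
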