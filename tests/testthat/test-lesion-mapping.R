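make_image_stack <- function(n, dims, fill = function() rnorm(prod(dims))) {
  lapply(seq_len(n), function(i) volume3d(array(fill(), dims), 2))
}

test_that("voxelwise correlation matches the closed form and flags degeneracy", {
  set.seed(1)
  dims <- c(3, 3, 3)
  n <- 6
  target <- rnorm(n)
  imgs <- make_image_stack(n, dims)
  for (i in seq_len(n)) {
    imgs[[i]]$data[1, 1, 1] <- target[i]        # perfect voxel
    imgs[[i]]$data[2, 1, 1] <- 7                # constant voxel
  }
  vc <- voxelwise_correlation(imgs, target)
  expect_equal(vc$r$data[1, 1, 1], 1, tolerance = 1e-12)
  expect_lt(vc$p$data[1, 1, 1], 1e-10)
  expect_true(vc$excluded[2, 1, 1])
  expect_true(is.na(vc$r$data[2, 1, 1]))
  # closed-form oracle at an arbitrary voxel
  v <- vapply(imgs, function(im) im$data[3, 2, 1], numeric(1))
  ct <- cor.test(v, target)
  expect_equal(vc$r$data[3, 2, 1], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(vc$p$data[3, 2, 1], ct$p.value, tolerance = 1e-10)
})

test_that("BH selection reproduces the hand-evaluated step-up rule", {
  expect_true(all(fdr_select(rep(0.001, 100), 0.05)))
  # p = {0.01, 0.02, 0.2, 0.9}, q = 0.05: k/m*q = .0125, .025, .0375, .05
  # largest k with p(k) <= kq/m is 2 -> select the first two
  expect_equal(fdr_select(c(0.01, 0.02, 0.2, 0.9), 0.05),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(fdr_select(c(0.9, 0.01, NA, 0.02), 0.05),
               c(FALSE, TRUE, FALSE, TRUE))
  expect_false(any(fdr_select(runif(50, 0.5, 1), 0.05)))
})

test_that("BH controls the false-discovery proportion under the null", {
  set.seed(10)
  fdp <- vapply(1:500, function(i) {
    sel <- fdr_select(runif(1000), 0.05)
    sum(sel) / max(sum(sel), 1)  # all discoveries are false under the null
  }, numeric(1))
  # E[FDP] equals q exactly under the all-null model; allow Monte-Carlo slack
  expect_lte(mean(fdp), 0.05 + 3 * sd(fdp) / sqrt(length(fdp)))
})

test_that("cluster extraction applies the strict volume threshold", {
  cfg <- vbcm_config(min_cluster_volume_mm3 = 2000)
  m <- array(FALSE, c(12, 12, 12))
  m[1:5, 1:5, 1:10] <- TRUE           # 250 voxels = 2000 mm^3 -> dropped
  rs <- extract_clusters(volume3d(m, 2), cfg)
  expect_length(rs$sizes, 0)
  m[1, 6, 1] <- TRUE                   # 251 voxels = 2008 mm^3 -> kept
  rs <- extract_clusters(volume3d(m, 2), cfg)
  expect_equal(rs$sizes, 251L)
  expect_gt(rs$volumes_mm3, 2000)
})

test_that("cluster labelling agrees with the flood-fill oracle", {
  set.seed(4)
  cfg <- vbcm_config(min_cluster_volume_mm3 = 7)  # keep clusters of > 0 voxels at 2 mm
  for (rep in 1:3) {
    m <- array(runif(7^3) < 0.3, c(7, 7, 7))
    rs <- extract_clusters(volume3d(m, 2), cfg)
    expect_true(same_partition(rs$labels$data, flood_fill_labels(m, "face")))
  }
})

test_that("lesion load is the mean abnormality within each ROI", {
  dims <- c(6, 6, 6)
  labs <- array(0L, dims)
  labs[1:2, 1:5, 1] <- 1L  # 10 voxels
  img <- array(0, dims)
  img[1, 1:5, 1] <- 1      # half of ROI 1 damaged
  expect_equal(lesion_load(volume3d(img, 2), volume3d(labs, 2)), 0.5)
  expect_equal(lesion_load(volume3d(array(1, dims), 2), volume3d(labs, 2)), 1)
  expect_equal(lesion_load(volume3d(array(0, dims), 2), volume3d(labs, 2)), 0)
  expect_error(lesion_load(volume3d(img, 2), volume3d(array(0L, dims), 2)),
               "empty")
})

test_that("LOOCV lesion model recovers a planted noise-free effect", {
  cfg <- recovery_config(seed = 22, n_rois = 8, n_tests = 8,
                         lesion_volume_range_mm3 = c(200, 1200))
  co <- simulate_cohort(cfg)
  abn <- lapply(co$lesions, `[[`, "abnormality")
  # target: exact affine function of the planted ROI's (continuous) lesion load
  roi1 <- volume3d(array(as.integer(co$atlas$data == co$truth$critical_roi_ids[1]),
                         cfg$grid_shape), cfg$voxel_size_mm)
  y <- 2 - 3 * vapply(abn, function(im) lesion_load(im, roi1), numeric(1))
  res <- loocv_lesion_model(abn, y,
                            vbcm_config(min_cluster_volume_mm3 = 1000,
                                        n_permutations = 0))
  expect_gt(res$accuracy_r, 0.95)
  expect_length(res$predicted, 60)
  expect_equal(res$residuals, res$actual - res$predicted)
})

test_that("no information leaks from the held-out subject", {
  cfg <- recovery_config(seed = 22, n_patients = 20)
  co <- simulate_cohort(cfg)
  y <- co$truth$latent_factors[, 1]
  abn <- lapply(co$lesions, `[[`, "abnormality")
  vb <- vbcm_config(min_cluster_volume_mm3 = 400, n_permutations = 0)
  res <- loocv_lesion_model(abn, y, vb)
  for (i in c(1, 7, 20)) {
    y2 <- y
    y2[i] <- y2[i] + 5  # perturb only the held-out subject's target
    res2 <- loocv_lesion_model(abn, y2, vb)
    expect_identical(res2$fold_artifacts[[i]]$labels$data,
                     res$fold_artifacts[[i]]$labels$data)
    expect_identical(res2$fold_coefs[[i]], res$fold_coefs[[i]])
    expect_equal(res2$predicted[i], res$predicted[i])
  }
})

test_that("permutation p-values follow the counting formula and are uniform under the null", {
  set.seed(6)
  target <- rnorm(20)
  runner <- function(y) cor(y, target)
  out <- permutation_pvalue(runner, target, n_perm = 1000, seed = 2)
  expect_equal(out$observed, 1)
  expect_equal(out$p, 1 / 1001)       # observed r above every null draw
  runner_low <- function(y) if (identical(y, target)) -1 else cor(y, target)
  out_low <- permutation_pvalue(runner_low, target, n_perm = 100, seed = 2)
  expect_equal(out_low$p, 1)          # observed below the whole null
  expect_error(permutation_pvalue(runner, target, n_perm = 0), "n_perm")

  set.seed(8)
  ps <- vapply(1:200, function(i) {
    yy <- rnorm(15)
    xx <- rnorm(15)
    permutation_pvalue(function(y) cor(y, xx), yy, n_perm = 99, seed = i)$p
  }, numeric(1))
  # p takes values k/100: compare bin counts against the uniform
  counts <- table(cut(ps, seq(0, 1, by = 0.25)))
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("stability maps count fold membership", {
  m <- array(FALSE, c(8, 8, 8))
  m[2:6, 2:6, 2:6] <- TRUE
  rs <- extract_clusters(volume3d(m, 2), vbcm_config(min_cluster_volume_mm3 = 10))
  sm <- stability_map(rep(list(rs), 10))
  expect_equal(max(sm$data), 10L)
  expect_equal(sum(sm$data == 10L), sum(m))
  expect_equal(sum(sm$data[!m]), 0L)
  empty <- extract_clusters(volume3d(array(FALSE, c(8, 8, 8)), 2),
                            vbcm_config(min_cluster_volume_mm3 = 10))
  expect_true(all(stability_map(list(empty, empty))$data == 0L))
})
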