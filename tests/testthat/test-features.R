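make_brain <- function(dims = c(8, 8, 8)) label_mask(array(1L, dims))

test_that("intensity normalization follows its contracts", {
  dims <- c(8, 8, 8)
  brain <- make_brain(dims)
  # uniform ramp: percentile mapping sends the midpoint near 0.5
  v <- volume3d(array(seq(10, 20, length.out = prod(dims)), dims))
  nv <- normalize_intensities(v, brain, "percentile_01_99")
  mid <- which.min(abs(v$data - 15))
  expect_equal(nv$data[mid], 0.5, tolerance = 0.02)
  expect_true(all(nv$data >= 0 & nv$data <= 1))
  # constant image collapses to 0, not an error
  cv <- volume3d(array(5, dims))
  expect_true(all(normalize_intensities(cv, brain)$data == 0))
  # z-score closed form and its degenerate error
  set.seed(1)
  z <- volume3d(array(rnorm(prod(dims), 5, 2), dims))
  nz <- normalize_intensities(z, brain, "zscore")
  mu <- mean(z$data); s <- sd(z$data)
  expect_equal(nz$data[1], (z$data[1] - mu) / s)
  expect_error(normalize_intensities(cv, brain, "zscore"), "degenerate")
  # outside-brain voxels are zeroed
  hb <- label_mask(array(c(1L, 0L), dims))
  nh <- normalize_intensities(v, hb, "zscore")
  expect_true(all(nh$data[hb$data == 0L] == 0))
})

test_that("patch means match a naive per-voxel oracle", {
  dims <- c(8, 8, 8)
  set.seed(2)
  vol <- volume3d(array(rnorm(prod(dims)), dims))
  brain <- label_mask(array(as.integer(runif(prod(dims)) < 0.8), dims))
  cfg <- feature_config("FLAIR", patch_size = 3,
                        intensity_normalization = "none")
  fm <- extract_features(list(FLAIR = vol), brain, cfg)
  naive <- vapply(seq_along(fm$voxel_index), function(r) {
    ijk <- arrayInd(fm$voxel_index[r], dims)
    rng <- lapply(1:3, function(a) max(1, ijk[a] - 1):min(dims[a], ijk[a] + 1))
    sub <- vol$data[rng[[1]], rng[[2]], rng[[3]]]
    msk <- brain$data[rng[[1]], rng[[2]], rng[[3]]]
    sum(sub[msk == 1L]) / sum(msk)
  }, numeric(1))
  expect_equal(unname(fm$x[, "FLAIR_patch"]), naive, tolerance = 1e-12)
})

test_that("degenerate and structured patch cases behave as documented", {
  dims <- c(3, 3, 3)
  brain <- make_brain(dims)
  # values 1..27 with a full 3-cube patch: centre mean is 14
  vol <- volume3d(array(1:27, dims))
  cfg <- feature_config("FLAIR", patch_size = 3,
                        intensity_normalization = "none")
  fm <- extract_features(list(FLAIR = vol), brain, cfg)
  ctr <- which(fm$voxel_index == 14L)
  expect_equal(unname(fm$x[ctr, "FLAIR_patch"]), 14)
  # constant image: patch column equals the intensity column
  cv <- volume3d(array(3, c(6, 6, 6)))
  fm2 <- extract_features(list(FLAIR = cv), make_brain(c(6, 6, 6)), cfg)
  expect_equal(fm2$x[, "FLAIR_patch"], fm2$x[, "FLAIR"])
})

test_that("feature-matrix geometry: row count, column layout, sw linearity", {
  s <- small_cohort(1, base_seed = 51)[[1]]
  brain <- s$masks$BRAIN
  cfg1 <- feature_config(c("FLAIR", "T1"), patch_size = 3, spatial_weighting = 1)
  fm1 <- extract_features(s$volumes, brain, cfg1)
  expect_equal(nrow(fm1$x), sum(brain$data))
  expect_identical(colnames(fm1$x),
                   c("FLAIR", "T1", "FLAIR_patch", "T1_patch", "x", "y", "z"))
  cfg2 <- cfg1; cfg2$spatial_weighting <- 2
  fm2 <- extract_features(s$volumes, brain, cfg2)
  expect_equal(fm2$x[, c("x", "y", "z")], 2 * fm1$x[, c("x", "y", "z")])
  # sw = 0 and patch = 0 drop their columns
  fm0 <- extract_features(s$volumes, brain, feature_config(c("FLAIR", "T1")))
  expect_identical(colnames(fm0$x), c("FLAIR", "T1"))
  expect_error(extract_features(s$volumes["T1"], brain, cfg1), "missing modality")
})

test_that("training-point sampling respects counts, pools and determinism", {
  s <- small_cohort(1, base_seed = 61)[[1]]
  gold <- s$masks$WMH_GOLD; brain <- s$masks$BRAIN
  n_gold <- sum(gold$data)

  pts <- sample_training_points(gold, brain, sampling_config("any"))
  expect_length(pts$lesion, n_gold)
  expect_length(pts$nonlesion, n_gold)
  expect_length(intersect(pts$lesion, pts$nonlesion), 0)
  expect_true(all(gold$data[pts$lesion] == 1L))
  expect_true(all(gold$data[pts$nonlesion] == 0L))

  pts2 <- sample_training_points(gold, brain, sampling_config("any"))
  expect_identical(pts, pts2)

  # noborder is a subset of any; surround and noborder are disjoint
  any_pts <- sample_training_points(gold, brain,
                                    sampling_config("any", 10, 100000))
  nb <- sample_training_points(gold, brain,
                               sampling_config("noborder", 10, 100000))
  sr <- sample_training_points(gold, brain,
                               sampling_config("surround", 10, 100000))
  expect_length(nb$warnings, 1)  # over-sized request records a warning
  expect_true(all(nb$nonlesion %in% any_pts$nonlesion))
  expect_length(intersect(nb$nonlesion, sr$nonlesion), 0)
})

test_that("the surround pool of an isolated voxel is its 26-neighbourhood", {
  dims <- c(9, 9, 9)
  g <- array(0L, dims); g[5, 5, 5] <- 1L
  gold <- label_mask(g, role = "WMH_GOLD")
  pts <- sample_training_points(gold, make_brain(dims),
                                sampling_config("surround", "ALL", 1000))
  expect_length(pts$nonlesion, 26)
  ijk <- arrayInd(pts$nonlesion, dims)
  expect_true(all(apply(abs(sweep(ijk, 2, c(5, 5, 5))), 1, max) == 1))
})

test_that("training samples never touch the stroke under input masking", {
  for (s in small_cohort(5, base_seed = 71)) {
    eff <- strokewmh:::effective_brain_mask(
      s, segmentation_settings(stroke_mode = "mask_input"))
    pts <- sample_training_points(s$masks$WMH_GOLD, eff,
                                  sampling_config("any", 100, 300))
    expect_true(all(s$masks$STROKE$data[c(pts$lesion, pts$nonlesion)] == 0L))
  }
})
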