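test_that("k-NN probabilities follow hand-computable toy cases", {
  # a query identical to a WMH training row, k = 1
  tr <- rbind(c(0, 0), c(5, 5))
  expect_equal(strokewmh:::cpp_knn_prob(tr, c(1L, 0L), rbind(c(0, 0)), 1), 1)
  # WMH {(0,0),(1,0)}, nonWMH {(10,0),(11,0)}, query (0.5, 0), k = 4
  tr2 <- rbind(c(0, 0), c(1, 0), c(10, 0), c(11, 0))
  expect_equal(strokewmh:::cpp_knn_prob(tr2, c(1L, 1L, 0L, 0L),
                                        rbind(c(0.5, 0)), 4), 0.5)
  # only non-WMH rows reachable
  expect_equal(strokewmh:::cpp_knn_prob(tr2[3:4, ], c(0L, 0L),
                                        rbind(c(0, 0)), 2), 0)
})

test_that("k-NN equals the exhaustive oracle and yields multiples of 1/k", {
  set.seed(8)
  for (i in 1:30) {
    ntr <- sample(20:400, 1); nq <- sample(5:150, 1)
    d <- sample(2:8, 1); k <- sample(1:min(30, ntr), 1)
    tr <- matrix(rnorm(ntr * d), ntr)
    qy <- matrix(rnorm(nq * d), nq)
    lab <- rbinom(ntr, 1, 0.5)
    p <- strokewmh:::cpp_knn_prob(tr, lab, qy, k)
    expect_identical(p, unname(knn_oracle(tr, lab, qy, k)))
    expect_true(all(abs(p * k - round(p * k)) < 1e-9))
  }
  # exact distance ties resolved identically (low-cardinality features)
  for (i in 1:10) {
    tr <- matrix(sample(0:2, 300 * 2, TRUE), 300)
    qy <- matrix(sample(0:2, 80 * 2, TRUE), 80)
    lab <- rbinom(300, 1, 0.5)
    expect_identical(strokewmh:::cpp_knn_prob(tr, lab, qy, 9),
                     unname(knn_oracle(tr, lab, qy, 9)))
  }
})

test_that("training-row permutation leaves tie-free predictions unchanged", {
  set.seed(9)
  tr <- matrix(rnorm(200 * 4), 200)
  lab <- rbinom(200, 1, 0.5)
  qy <- matrix(rnorm(50 * 4), 50)
  perm <- sample(200)
  expect_identical(strokewmh:::cpp_knn_prob(tr, lab, qy, 11),
                   strokewmh:::cpp_knn_prob(tr[perm, ], lab[perm], qy, 11))
})

test_that("binarize uses an inclusive threshold and nests with tau", {
  p <- volume3d(array(c(0.80, 0.85, 0.90, 0), c(2, 2, 1)), modality = "PROB")
  expect_identical(as.vector(binarize(p, 0.85)$data), c(0L, 1L, 1L, 0L))
  set.seed(10)
  pr <- volume3d(array(runif(6^3), c(6, 6, 6)), modality = "PROB")
  prev <- binarize(pr, 0.8)$data
  for (tau in c(0.85, 0.9, 0.95, 0.99)) {
    cur <- binarize(pr, tau)$data
    expect_true(all(prev[cur == 1L] == 1L))  # never gains voxels
    prev <- cur
  }
  expect_error(binarize(pr, 1.2), "tau")
})

test_that("fitting concatenates sampled rows with the expected counts", {
  co <- small_cohort(2, base_seed = 81)
  n_gold <- sum(co[[1]]$masks$WMH_GOLD$data)
  set1 <- segmentation_settings(
    feature_config = feature_config(c("FLAIR", "T1")),
    sampling_config = sampling_config("any", "ALL", "EQUAL"), k = 15)
  m1 <- wmh_knn(co[1], set1)
  expect_equal(nrow(m1$x), 2 * n_gold)
  expect_equal(sum(m1$y), n_gold)
  # two identical subjects duplicate the rows (same per-subject seeds apart)
  m2 <- wmh_knn(list(co[[1]], co[[1]]), set1)
  expect_equal(nrow(m2$x), 4 * n_gold)
  # no training voxel inside the stroke under input masking
  mI <- wmh_knn(co, quick_settings(stroke_mode = "mask_input"))
  expect_s3_class(mI, "wmh_knn")
  expect_error(wmh_knn(co, quick_settings(k = 1e6)), "k exceeds")
})

test_that("segmentation handles stroke on input or output correctly", {
  co <- small_cohort(3, base_seed = 91)
  target <- co[[3]]
  mI <- wmh_knn(co[1:2], quick_settings(stroke_mode = "mask_input"))
  mO <- wmh_knn(co[1:2], quick_settings(stroke_mode = "mask_output"))
  segI <- segment_subject(mI, target)
  segO <- segment_subject(mO, target)
  st <- target$masks$STROKE$data
  expect_true(all(segI$mask$data[st == 1L] == 0L))
  expect_true(all(segO$mask$data[st == 1L] == 0L))
  expect_true(all(segI$prob$data[st == 1L] == 0))
  # output dilation clears the dilated ring too
  setD <- quick_settings(stroke_mode = "mask_output", output_dilation_mm = 3)
  mD <- wmh_knn(co[1:2], setD)
  segD <- segment_subject(mD, target)
  ring <- dilate_mask(target$masks$STROKE, 3)$data
  expect_true(all(segD$mask$data[ring == 1L] == 0L))
  # probabilities are multiples of 1/k and in [0, 1]
  pv <- segI$prob$data[target$masks$BRAIN$data == 1L & st == 0L]
  expect_true(all(abs(pv * mI$k - round(pv * mI$k)) < 1e-9))
})

test_that("an empty stroke mask makes both stroke modes identical", {
  co <- small_cohort(3, base_seed = 101, stroke_present = FALSE)
  mI <- wmh_knn(co[1:2], quick_settings(stroke_mode = "mask_input"))
  mO <- wmh_knn(co[1:2], quick_settings(stroke_mode = "mask_output"))
  segI <- segment_subject(mI, co[[3]])
  segO <- segment_subject(mO, co[[3]])
  expect_identical(segI$prob$data, segO$prob$data)
  expect_identical(segI$mask$data, segO$mask$data)
})

test_that("feature or stroke-mask mismatches are configuration errors", {
  co <- small_cohort(2, base_seed = 111)
  m <- wmh_knn(co[1], quick_settings())
  other <- segmentation_settings(
    feature_config = feature_config(c("FLAIR", "T1"), patch_size = 3),
    sampling_config = sampling_config("any", 100, 200), k = 15)
  expect_error(segment_subject(m, co[[2]], other), "feature mismatch")
  s_nostroke <- co[[2]]; s_nostroke$masks$STROKE <- NULL
  expect_error(segment_subject(m, s_nostroke), "stroke")
})
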