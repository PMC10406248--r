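mask_from <- function(idx, dims = c(8, 8, 8)) {
  a <- array(0L, dims); a[idx] <- 1L
  label_mask(a)
}

test_that("voxel metrics match hand-enumerated fixtures", {
  m <- mask_from(1:10)
  expect_equal(voxel_metrics(m, m), c(SI = 1, FDR = 0, FNR = 0))
  # |G| = 4, |A| = 6, |G & A| = 3
  g <- mask_from(c(1, 2, 3, 4))
  a <- mask_from(c(2, 3, 4, 10, 11, 12))
  expect_equal(voxel_metrics(g, a), c(SI = 0.6, FDR = 0.5, FNR = 0.25))
  # disjoint non-empty masks
  expect_equal(voxel_metrics(mask_from(1:3), mask_from(10:12)),
               c(SI = 0, FDR = 1, FNR = 1))
  # undefined-ness flags
  empty <- mask_from(integer(0))
  expect_true(is.nan(voxel_metrics(g, empty)["FDR"]))
  expect_true(all(is.nan(voxel_metrics(empty, a)[c("SI", "FNR")])))
})

test_that("cluster metrics match hand fixtures and the pairing oracle", {
  g <- mask_from(1:4)
  expect_equal(cluster_metrics(g, g), c(FDRc = 0, FNRc = 0, DER = 0, OER = 0))
  # A has 2 clusters, one overlapping G
  dims <- c(10, 10, 1)
  g2 <- mask_from(c(11, 12), dims)          # voxels (1:2, 2)
  a2 <- label_mask(array(0L, dims))
  a2$data[1, 2, 1] <- 1L                    # overlaps g2
  a2$data[8:9, 8, 1] <- 1L                  # far cluster, no overlap
  cm <- cluster_metrics(g2, a2)
  expect_equal(unname(cm["FDRc"]), 0.5)
  expect_equal(unname(cm["FNRc"]), 0)
  # one 8-voxel cluster vs the same shifted to overlap in 4 voxels
  g3 <- label_mask(array(0L, dims)); g3$data[1:2, 1:4, 1] <- 1L
  a3 <- label_mask(array(0L, dims)); a3$data[2:3, 1:4, 1] <- 1L
  cm3 <- cluster_metrics(g3, a3)
  expect_equal(unname(cm3["OER"]), 1)
  expect_equal(unname(cm3["DER"]), 0)

  set.seed(16)
  for (i in 1:30) {
    gm <- random_mask(c(16, 16, 16), p = runif(1, 0.02, 0.15))
    am <- random_mask(c(16, 16, 16), p = runif(1, 0.02, 0.15))
    got <- cluster_metrics(gm, am)
    want <- cluster_metrics_oracle(gm, am)
    expect_equal(got, want, tolerance = 1e-12)
    # Wack-style identity: DER + OER = (FP + FN) / MTA
    fpfn <- sum(gm$data != am$data)
    mta <- (sum(gm$data) + sum(am$data)) / 2
    expect_equal(unname(got["DER"] + got["OER"]), fpfn / mta,
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant to joint translation of both masks", {
  set.seed(17)
  g <- array(0L, c(12, 12, 12)); g[3:5, 3:5, 3:5] <- 1L
  a <- array(0L, c(12, 12, 12)); a[4:6, 3:5, 3:5] <- 1L
  shift <- function(x) { y <- array(0L, dim(x)); y[4:12, 4:12, 4:12] <- x[1:9, 1:9, 1:9]; y }
  expect_equal(voxel_metrics(label_mask(g), label_mask(a)),
               voxel_metrics(label_mask(shift(g)), label_mask(shift(a))))
  expect_equal(cluster_metrics(label_mask(g), label_mask(a)),
               cluster_metrics(label_mask(shift(g)), label_mask(shift(a))))
})

test_that("ICC(A,1) matches the ANOVA oracle and its boundary behaviour", {
  v <- c(10, 20, 30, 40)
  expect_equal(icc_agreement(v, v), 1)
  # constant offset: penalized below 1, exact value from the ANOVA oracle
  expect_lt(icc_agreement(v, v + 10), 1)
  expect_equal(icc_agreement(v, v + 10), icc_oracle_aov(v, v + 10),
               tolerance = 1e-10)
  set.seed(18)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    g <- rnorm(n, 50, 20); a <- g * runif(1, 0.5, 1.5) + rnorm(n, 0, 5)
    expect_equal(icc_agreement(g, a), icc_oracle_aov(g, a), tolerance = 1e-10)
  }
  # vanishing disagreement drives the ICC to 1
  g <- rnorm(200, 100, 30)
  expect_gt(icc_agreement(g, g + rnorm(200, 0, 1e-4)), 0.999)
  expect_error(icc_agreement(1:2, 1:2), "at least 3")
  expect_error(icc_agreement(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("cohort reports aggregate correctly and keep the column order", {
  g1 <- mask_from(1:4); a1 <- mask_from(c(2, 3, 4, 10, 11, 12))
  rep1 <- cohort_report(list(s1 = list(gold = g1, auto = a1)))
  expect_equal(unname(rep1$means["SI"]), 0.6)
  expect_true(is.na(rep1$icc))
  expect_identical(
    colnames(rep1$subjects),
    c("subject", "SI", "FDR", "FNR", "FDRc", "FNRc", "DER", "OER",
      "gold_mm3", "auto_mm3"))
  # means over defined values only
  rep2 <- cohort_report(list(
    list(gold = g1, auto = a1),
    list(gold = g1, auto = mask_from(integer(0)))))
  expect_equal(unname(rep2$means["FDR"]), 0.5)  # NaN subject excluded
  expect_equal(unname(rep2$n_undefined["FDR"]), 1L)
  expect_equal(unname(rep2$means["SI"]), mean(c(0.6, 0)))
  # CSV round trip with a means row
  f <- withr::local_tempfile(fileext = ".csv")
  rep3 <- cohort_report(list(list(gold = g1, auto = a1),
                             list(gold = g1, auto = g1),
                             list(gold = a1, auto = a1)))
  write_report(rep3, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 4)
  expect_equal(df$subject[4], "MEAN")
  expect_equal(df$ICC[4], rep3$icc, tolerance = 1e-12)
})

test_that("voxel error rates move monotonically with tau on calibrated maps", {
  # deterministic, calibrated map: gold probabilities span 0.5..1, non-gold
  # span 0..0.9, so precision rises with the threshold
  dims <- c(10, 10, 10)
  set.seed(19)
  gold <- random_mask(dims, p = 0.2)
  p <- array(0, dims)
  ng <- sum(gold$data); nn <- prod(dims) - ng
  p[gold$data == 1L] <- seq(0.5, 1, length.out = ng)
  p[gold$data == 0L] <- seq(0, 0.9, length.out = nn)
  pv <- volume3d(p, modality = "PROB")
  taus <- c(0.8, 0.85, 0.9, 0.95, 0.99)
  vm <- t(vapply(taus, function(tau)
    voxel_metrics(gold, binarize(pv, tau)), numeric(3)))
  expect_true(all(diff(vm[, "FDR"]) <= 1e-12))
  expect_true(all(diff(vm[, "FNR"]) >= -1e-12))
})
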