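test_that("NIfTI round trip preserves data, voxel size and affine", {
  set.seed(1)
  aff <- diag(c(1, 1.5, 2, 1)); aff[1:3, 4] <- c(-12, 7, 3)
  v <- volume3d(array(rnorm(8^3), c(8, 8, 8)), c(1, 1.5, 2), aff, "FLAIR")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f, "FLAIR")
  expect_equal(v2$data, v$data, tolerance = 1e-12)
  expect_equal(v2$voxel_size, v$voxel_size, tolerance = 1e-6)
  expect_equal(v2$affine, v$affine, tolerance = 1e-5, ignore_attr = TRUE)

  m <- label_mask(array(as.integer(runif(8^3) < 0.3), c(8, 8, 8)),
                  c(1, 1.5, 2), aff, "WMH_GOLD")
  fm <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(m, fm)
  m2 <- read_mask(fm, "WMH_GOLD")
  expect_true(all(m2$data %in% c(0L, 1L)))
  expect_identical(m2$data, m$data)
})

test_that("reading a 4-D file is a dimension error", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), f)
  expect_error(read_volume(f), "3-D")
})

test_that("plain-text affine files parse and reject bad input", {
  f <- withr::local_tempfile(fileext = ".mat")
  m <- diag(4); m[1:3, 4] <- c(2, -1, 0.5)
  writeLines(apply(m, 1, paste, collapse = " "), f)
  expect_equal(read_affine_matrix(f), m)
  writeLines("1 2 3", f)
  expect_error(read_affine_matrix(f), "16 numbers")
})

test_that("resampling: identity is exact, integer shifts match index shifts", {
  set.seed(2)
  v <- volume3d(array(rnorm(6^3), c(6, 6, 6)))
  expect_identical(resample_affine(v)$data, v$data)

  # translation by exactly one voxel along axis 1, nearest interpolation
  m <- array(0L, c(6, 6, 6)); m[3, 4, 2] <- 1L
  msk <- label_mask(m)
  tr <- diag(4); tr[1, 4] <- 1  # +1 mm world shift = +1 voxel at 1 mm
  shifted <- resample_affine(msk, tr)
  expect_true(all(shifted$data %in% c(0L, 1L)))
  expect_equal(which(shifted$data == 1L), which(m == 1L) + 1L)

  # trilinear resampling of a constant volume stays constant (interior)
  cv <- volume3d(array(7, c(6, 6, 6)))
  tr2 <- diag(4); tr2[1:3, 4] <- c(0.3, -0.2, 0.45)
  out <- resample_affine(cv, tr2, interpolation = "trilinear")
  expect_equal(out$data[2:5, 2:5, 2:5], array(7, c(4, 4, 4)))

  expect_error(resample_affine(v, matrix(0, 4, 4)), "singular")
})

test_that("physical dilation honours the mm radius and anisotropy", {
  m <- array(0L, c(7, 7, 7)); m[4, 4, 4] <- 1L
  msk <- label_mask(m)
  expect_identical(dilate_mask(msk, 0)$data, m)
  # 1 mm isotropic, radius 1 mm: centre + 6 face neighbours
  d1 <- dilate_mask(msk, 1)
  expect_equal(sum(d1$data), 7)
  # anisotropic: 2 mm along z means radius 1 mm adds no z neighbours
  msk_an <- label_mask(m, voxel_size = c(1, 1, 2))
  expect_equal(sum(dilate_mask(msk_an, 1)$data), 5)
  # a full mask cannot grow
  full <- label_mask(array(1L, c(5, 5, 5)))
  expect_identical(dilate_mask(full, 2)$data, full$data)
  expect_error(dilate_mask(msk, -1), ">= 0")
})

test_that("dilation is monotone in the radius", {
  set.seed(3)
  for (i in 1:20) {
    m <- random_mask(c(9, 9, 9), p = 0.05)
    if (sum(m$data) == 0) next
    r <- sort(runif(2, 0, 4))
    a <- dilate_mask(m, r[1])$data
    b <- dilate_mask(m, r[2])$data
    expect_true(all(b[a == 1L] == 1L))
    expect_true(all(a[m$data == 1L] == 1L))
  }
})

test_that("connected components match the flood-fill oracle exhaustively", {
  # all 2^9 masks on a 3x3x1 grid, both 6- and 26-adjacency
  for (bits in 0:511) {
    arr <- array(as.integer(bitwAnd(bitwShiftR(bits, 0:8), 1L)), c(3, 3, 1))
    m <- label_mask(arr)
    for (conn in c(6, 26)) {
      got <- connected_components(m, conn)
      want <- flood_fill_components(arr, conn)
      expect_equal(got$n, want$n)
      # same partition (labels may differ): compare co-membership
      if (want$n > 0) {
        expect_equal(outer(got$labels[arr == 1L], got$labels[arr == 1L], `==`),
                     outer(want$labels[arr == 1L], want$labels[arr == 1L], `==`))
      }
    }
  }
})

test_that("corner-touching voxels join under 26- but not 6-adjacency", {
  arr <- array(0L, c(2, 2, 2)); arr[1, 1, 1] <- 1L; arr[2, 2, 2] <- 1L
  m <- label_mask(arr)
  expect_equal(connected_components(m, 26)$n, 1)
  expect_equal(connected_components(m, 6)$n, 2)
  expect_equal(connected_components(label_mask(array(0L, c(3, 3, 3))))$n, 0)
})

test_that("connected components agree with the oracle on random grids", {
  set.seed(4)
  for (i in 1:5) {
    m <- random_mask(c(16, 16, 16), p = 0.2)
    expect_equal(connected_components(m, 26)$n,
                 flood_fill_components(m$data, 26)$n)
    expect_equal(connected_components(m, 6)$n,
                 flood_fill_components(m$data, 6)$n)
  }
})

test_that("distance transform is exact", {
  m <- array(0L, c(5, 5, 5)); m[3, 3, 3] <- 1L
  d <- distance_to_mask(label_mask(m))$data
  expect_equal(d[4, 3, 3], 1)            # face neighbour at 1 mm
  expect_equal(d[4, 4, 4], sqrt(3))      # body diagonal
  expect_equal(d[3, 3, 3], 0)
  expect_error(distance_to_mask(label_mask(array(0L, c(3, 3, 3)))), "empty")

  set.seed(5)
  for (vs in list(c(1, 1, 1), c(1, 1.7, 2.3))) {
    m <- random_mask(c(12, 12, 12), p = 0.04, voxel_size = vs)
    if (sum(m$data) == 0) next
    expect_lt(max(abs(distance_to_mask(m)$data - brute_edt(m$data, vs))), 1e-9)
  }
})

test_that("grid compatibility is enforced", {
  a <- volume3d(array(0, c(4, 4, 4)))
  b <- volume3d(array(0, c(4, 4, 5)))
  expect_error(strokewmh:::check_same_grid(a, b), "shape")
  cc <- volume3d(array(0, c(4, 4, 4)), affine = diag(c(2, 1, 1, 1)))
  expect_error(strokewmh:::check_same_grid(a, cc), "affine")
})
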