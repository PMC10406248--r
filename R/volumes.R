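#' @useDynLib strokewmh, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats kmeans quantile rnorm runif sd var
#' @importFrom utils read.csv write.csv tail
NULL

MODALITIES <- c("FLAIR", "T1", "T2", "PROB", "OTHER")
MASK_ROLES <- c("WMH_GOLD", "STROKE", "BRAIN", "VENTRICLE", "WMH_AUTO")

#' Scalar 3-D image volume
#'
#' Container for a single-modality 3-D image: a numeric array plus the voxel
#' size in mm and the 4x4 voxel-to-world (NIfTI-style) affine. Voxel indices
#' are 0-based when mapped through the affine.
#'
#' @param data 3-D numeric array.
#' @param voxel_size length-3 positive numeric, mm per voxel along each axis.
#' @param affine 4x4 invertible voxel-to-world matrix; default is a diagonal
#'   scaling by `voxel_size` with the origin at voxel (0,0,0).
#' @param modality one of `"FLAIR"`, `"T1"`, `"T2"`, `"PROB"`, `"OTHER"`.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, voxel_size = c(1, 1, 1), affine = NULL,
                     modality = "OTHER") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3-D array", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three positive values (mm)", call. = FALSE)
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4x4 matrix", call. = FALSE)
  modality <- match.arg(modality, MODALITIES)
  structure(list(data = data, voxel_size = voxel_size, affine = affine,
                 modality = modality),
            class = "volume3d")
}

#' Binary 3-D mask
#'
#' A `volume3d`-compatible binary mask with a semantic role (gold-standard
#' WMH, stroke lesion, brain, ventricles, or automated WMH output).
#'
#' @param data 3-D array with values in \{0, 1\} (logical accepted).
#' @inheritParams volume3d
#' @param role one of `"WMH_GOLD"`, `"STROKE"`, `"BRAIN"`, `"VENTRICLE"`,
#'   `"WMH_AUTO"`.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(data, voxel_size = c(1, 1, 1), affine = NULL,
                       role = "WMH_AUTO") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask data must be a 3-D array", call. = FALSE)
  v <- as.vector(data)
  if (!all(v %in% c(0, 1)))
    stop("mask values must be 0/1", call. = FALSE)
  role <- match.arg(role, MASK_ROLES)
  vol <- volume3d(array(as.integer(v), dim(data)), voxel_size, affine, "OTHER")
  structure(list(data = vol$data, voxel_size = vol$voxel_size,
                 affine = vol$affine, role = role),
            class = "label_mask")
}

is_mask <- function(x) inherits(x, "label_mask")

vox_volume_mm3 <- function(x) prod(x$voxel_size)

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d %s  %s  voxels %s mm>\n", x$modality,
              paste(dim(x$data), collapse = "x"),
              paste(format(x$voxel_size), collapse = "x")))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask %s  %s  |mask| = %d (%.1f mm3)>\n", x$role,
              paste(dim(x$data), collapse = "x"), sum(x$data),
              sum(x$data) * vox_volume_mm3(x)))
  invisible(x)
}

# Shape must match exactly; affines within 1e-4 elementwise. Mismatch is an
# error, never silent resampling.
check_same_grid <- function(a, b, tol = 1e-4) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("volumes are not on the same grid (shape mismatch)", call. = FALSE)
  if (max(abs(a$affine - b$affine)) > tol)
    stop("volumes are not on the same grid (affine mismatch)", call. = FALSE)
  invisible(TRUE)
}

# world-mm coordinates of every voxel (0-based indices through the affine);
# returns an n x 3 matrix in linear-index order.
grid_world_coords <- function(vol) {
  d <- dim(vol$data)
  idx <- arrayInd(seq_len(prod(d)), d) - 1L
  h <- cbind(idx, 1) %*% t(vol$affine)
  h[, 1:3, drop = FALSE]
}

# Evaluate .Random.seed-safe code under a local seed.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---- NIfTI I/O -----------------------------------------------------------

#' Read a 3-D NIfTI volume
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @param modality modality tag to attach (see [volume3d()]).
#' @return A [volume3d()].
#' @export
read_volume <- function(path, modality = "OTHER") {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file: ",
                                           conditionMessage(e), call. = FALSE))
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3-D volume, got %d dimensions", length(d)),
         call. = FALSE)
  aff <- unclass(RNifti::xform(img))[1:4, 1:4]
  volume3d(array(as.numeric(img), d), RNifti::pixdim(img), aff, modality)
}

#' Read a binary NIfTI mask
#'
#' @inheritParams read_volume
#' @param role mask role tag (see [label_mask()]).
#' @return A [label_mask()].
#' @export
read_mask <- function(path, role = "WMH_AUTO") {
  v <- read_volume(path)
  label_mask(v$data, v$voxel_size, v$affine, role)
}

#' Write a volume or mask to NIfTI
#'
#' Writing then reading back reproduces data, voxel size and affine.
#'
#' @param vol a [volume3d()] or [label_mask()].
#' @param path destination `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  dt <- if (is_mask(vol)) "uint8" else "double"
  img <- RNifti::asNifti(vol$data,
                         list(pixdim = c(-1, vol$voxel_size, 0, 0, 0, 0)),
                         datatype = dt)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a plain-text 4x4 affine matrix
#'
#' FLIRT-style `.mat` dialect: 16 whitespace-separated numbers, row-major.
#'
#' @param path text file with the matrix.
#' @return 4x4 numeric matrix.
#' @export
read_affine_matrix <- function(path) {
  v <- scan(path, what = numeric(), quiet = TRUE)
  if (length(v) != 16L)
    stop("affine file must contain exactly 16 numbers", call. = FALSE)
  m <- matrix(v, 4, 4, byrow = TRUE)
  if (abs(det(m)) < 1e-12) stop("affine matrix is singular", call. = FALSE)
  m
}

# ---- resampling ----------------------------------------------------------

#' Resample a volume through a linear transform
#'
#' Applies a given world-to-world affine (e.g. a linear registration to a
#' template space) by pull-back interpolation onto a target grid. Only the
#' application of transforms is supported; estimating them is out of scope.
#'
#' @param vol a [volume3d()] or [label_mask()].
#' @param transform 4x4 world-to-world matrix mapping source world
#'   coordinates to target world coordinates (identity by default).
#' @param target_grid list with `shape` (length-3 integer), `voxel_size` and
#'   `affine`; defaults to the source grid.
#' @param interpolation `"trilinear"` (intensity volumes) or `"nearest"`
#'   (masks). Masks are always resampled nearest so binarity is preserved.
#' @return A [volume3d()] or [label_mask()] on the target grid.
#' @export
resample_affine <- function(vol, transform = diag(4), target_grid = NULL,
                            interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  mask_in <- is_mask(vol)
  if (mask_in) interpolation <- "nearest"
  transform <- as.matrix(transform)
  if (abs(det(transform)) < 1e-12)
    stop("invalid transform: singular matrix", call. = FALSE)
  if (is.null(target_grid))
    target_grid <- list(shape = dim(vol$data), voxel_size = vol$voxel_size,
                        affine = vol$affine)
  shp <- as.integer(target_grid$shape)

  # target voxel -> target world -> source world -> source voxel
  map <- solve(vol$affine) %*% solve(transform) %*% target_grid$affine
  idx <- arrayInd(seq_len(prod(shp)), shp) - 1L
  src <- cbind(idx, 1) %*% t(map)
  x <- src[, 1]; y <- src[, 2]; z <- src[, 3]
  d <- dim(vol$data)
  dat <- vol$data

  pick <- function(i, j, k) {
    ok <- i >= 0L & i < d[1] & j >= 0L & j < d[2] & k >= 0L & k < d[3]
    out <- numeric(length(i))
    lin <- 1L + i[ok] + d[1] * (j[ok] + d[2] * k[ok])
    out[ok] <- dat[lin]
    out
  }

  if (interpolation == "nearest") {
    vals <- pick(as.integer(round(x)), as.integer(round(y)),
                 as.integer(round(z)))
  } else {
    x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
    fx <- x - x0; fy <- y - y0; fz <- z - z0
    i0 <- as.integer(x0); j0 <- as.integer(y0); k0 <- as.integer(z0)
    vals <- 0
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      w <- (if (a) fx else 1 - fx) * (if (b) fy else 1 - fy) *
        (if (cc) fz else 1 - fz)
      vals <- vals + w * pick(i0 + a, j0 + b, k0 + cc)
    }
  }
  arr <- array(vals, shp)
  if (mask_in)
    label_mask(arr, target_grid$voxel_size, target_grid$affine, vol$role)
  else
    volume3d(arr, target_grid$voxel_size, target_grid$affine, vol$modality)
}

# ---- morphology / geometry ----------------------------------------------

#' Dilate a mask by a physical radius
#'
#' Grows the mask to every voxel whose centre lies within `radius_mm`
#' (Euclidean, honouring anisotropic voxel sizes) of a mask voxel centre.
#' Used e.g. to dilate stroke-lesion masks in 1 mm steps before removing
#' them from segmenter output.
#'
#' @param mask a [label_mask()].
#' @param radius_mm non-negative dilation radius in mm.
#' @return The dilated [label_mask()]; always a superset of the input.
#' @export
dilate_mask <- function(mask, radius_mm) {
  if (!is_mask(mask)) stop("mask must be a label_mask", call. = FALSE)
  if (!is.numeric(radius_mm) || radius_mm < 0)
    stop("radius_mm must be >= 0", call. = FALSE)
  if (radius_mm == 0 || sum(mask$data) == 0L) return(mask)
  d <- cpp_edt(as.integer(mask$data), dim(mask$data), mask$voxel_size)
  out <- array(as.integer(d <= radius_mm + 1e-9), dim(mask$data))
  label_mask(out, mask$voxel_size, mask$affine, mask$role)
}

# 1-voxel 26-neighbourhood dilation (voxel lattice, not mm); the "border"
# used by the noborder/surround sampling policies.
dilate_voxel26 <- function(mask) {
  if (sum(mask$data) == 0L) return(mask)
  d <- cpp_edt(as.integer(mask$data), dim(mask$data), c(1, 1, 1))
  out <- array(as.integer(d <= sqrt(3) + 1e-9), dim(mask$data))
  label_mask(out, mask$voxel_size, mask$affine, mask$role)
}

#' Label connected components of a mask
#'
#' @param mask a [label_mask()].
#' @param connectivity voxel adjacency: 6 (faces), 18 (+edges) or
#'   26 (+corners, the default used for lesion clusters).
#' @return A list with `labels` (integer array, 0 = background, components
#'   numbered 1..n) and `n` (component count).
#' @export
connected_components <- function(mask, connectivity = 26) {
  if (!is_mask(mask)) stop("mask must be a label_mask", call. = FALSE)
  lab <- cpp_label_components(as.integer(mask$data), dim(mask$data),
                              as.integer(connectivity))
  list(labels = array(as.integer(lab), dim(mask$data)),
       n = attr(lab, "n_components"))
}

#' Euclidean distance to a mask
#'
#' Exact distance (mm) from every voxel centre to the nearest mask voxel
#' centre; 0 inside the mask. Used to build distance-from-ventricle maps for
#' spatially adaptive thresholding and periventricular/deep splits.
#'
#' @param mask a non-empty [label_mask()].
#' @return A [volume3d()] of distances in mm.
#' @export
distance_to_mask <- function(mask) {
  if (!is_mask(mask)) stop("mask must be a label_mask", call. = FALSE)
  if (sum(mask$data) == 0L)
    stop("distance_to_mask: mask is empty", call. = FALSE)
  d <- cpp_edt(as.integer(mask$data), dim(mask$data), mask$voxel_size)
  volume3d(array(d, dim(mask$data)), mask$voxel_size, mask$affine, "OTHER")
}
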