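# Per-voxel feature construction for the k-NN segmenter: modality
# intensities, cubic-patch local means, and spatially weighted template
# coordinates; plus training-point sampling with the any/noborder/surround
# location policies.

#' Feature-space configuration
#'
#' Defines the per-voxel feature vector: the ordered modalities used as
#' intensity features (FLAIR always first and required), an optional cubic
#' patch of side `patch_size` voxels whose within-brain mean intensity is
#' appended per modality, and an optional spatial-weighting factor `sw`
#' multiplying normalised template coordinates. `sw` is a linear scaling
#' factor: larger values make location dominate neighbour distances.
#'
#' @param modalities ordered character subset of `c("FLAIR","T1","T2")`.
#' @param patch_size cubic patch side in voxels; 0 = no patch features.
#'   The tested grid is `{0, 3, 6, 9}` but any non-negative integer works.
#' @param spatial_weighting `sw >= 0`; 0 drops the spatial columns. Tested
#'   grid `{0, 1, 5, 10}`.
#' @param intensity_normalization `"percentile_01_99"` (clip to the within-
#'   brain 1st/99th percentiles then map to `[0, 1]`), `"zscore"`, or
#'   `"none"`.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(modalities = c("FLAIR", "T1"), patch_size = 0,
                           spatial_weighting = 0,
                           intensity_normalization = c("percentile_01_99",
                                                       "zscore", "none")) {
  modalities <- match.arg(modalities, c("FLAIR", "T1", "T2"),
                          several.ok = TRUE)
  if (!"FLAIR" %in% modalities)
    stop("FLAIR must be among the feature modalities", call. = FALSE)
  if (patch_size < 0 || spatial_weighting < 0)
    stop("patch_size and spatial_weighting must be >= 0", call. = FALSE)
  structure(list(modalities = modalities,
                 patch_size = as.integer(patch_size),
                 spatial_weighting = spatial_weighting,
                 intensity_normalization = match.arg(intensity_normalization)),
            class = "feature_config")
}

#' Training-point sampling configuration
#'
#' @param location non-lesion candidate pool: `"any"` (anywhere in the
#'   brain outside the WMH mask), `"noborder"` (additionally excluding the
#'   1-voxel 26-neighbourhood border of the WMH mask), or `"surround"`
#'   (only that border).
#' @param n_lesion `"ALL"` (every gold voxel) or a positive count of lesion
#'   training points drawn uniformly without replacement.
#' @param n_nonlesion `"EQUAL"` (match the drawn lesion count) or a count.
#' @param seed RNG seed making draws deterministic.
#' @return An object of class `sampling_config`.
#' @export
sampling_config <- function(location = c("any", "noborder", "surround"),
                            n_lesion = "ALL", n_nonlesion = "EQUAL",
                            seed = 1) {
  location <- match.arg(location)
  chk <- function(x, kw) {
    if (is.character(x)) {
      if (!identical(toupper(x), kw)) stop("invalid count: ", x, call. = FALSE)
      return(kw)
    }
    if (!is.numeric(x) || x < 1) stop("counts must be positive", call. = FALSE)
    as.integer(x)
  }
  structure(list(location = location, n_lesion = chk(n_lesion, "ALL"),
                 n_nonlesion = chk(n_nonlesion, "EQUAL"),
                 seed = as.integer(seed)),
            class = "sampling_config")
}

#' Normalize image intensities within the brain
#'
#' @param vol a [volume3d()].
#' @param brain a non-empty brain [label_mask()].
#' @param method `"percentile_01_99"`, `"zscore"` or `"none"`. The
#'   percentile method clips to the within-brain q01/q99 and maps to
#'   `[0, 1]`; a constant image (q01 = q99) maps to 0. Voxels outside the
#'   brain are set to 0.
#' @return A normalized [volume3d()].
#' @export
normalize_intensities <- function(vol, brain,
                                  method = c("percentile_01_99", "zscore",
                                             "none")) {
  method <- match.arg(method)
  check_same_grid(vol, brain)
  inb <- brain$data == 1L
  if (!any(inb)) stop("brain mask is empty", call. = FALSE)
  v <- vol$data
  out <- array(0, dim(v))
  if (method == "none") {
    out[inb] <- v[inb]
  } else if (method == "percentile_01_99") {
    q <- quantile(v[inb], c(0.01, 0.99), names = FALSE, type = 7)
    if (q[2] <= q[1]) {
      out[inb] <- 0
    } else {
      out[inb] <- (pmin(pmax(v[inb], q[1]), q[2]) - q[1]) / (q[2] - q[1])
    }
  } else {
    mu <- mean(v[inb]); s <- sd(v[inb])
    if (!is.finite(s) || s == 0)
      stop("degenerate image: zero within-brain variance", call. = FALSE)
    out[inb] <- (v[inb] - mu) / s
  }
  volume3d(out, vol$voxel_size, vol$affine, vol$modality)
}

# patch window offsets: side p centred on the voxel; for even p the shorter
# half-width goes to the origin side (lo = floor((p-1)/2), hi = p-1-lo)
patch_halfwidths <- function(p) {
  lo <- (p - 1L) %/% 2L
  c(lo = lo, hi = p - 1L - lo)
}

#' Extract the per-voxel feature matrix
#'
#' One row per voxel of `effective_brain` in linear-index order. Columns:
#' normalized intensity per modality; the mean over the cubic patch
#' intersected with `effective_brain` per modality (if `patch_size > 0`);
#' and `sw`-scaled normalized template coordinates (if `sw > 0`). Template
#' coordinates are world-mm offsets from the grid centre divided by the
#' grid half-extent, so they share the scale of normalized intensities and
#' `sw` acts as a pure relative weighting.
#'
#' @param volumes named list of [volume3d()]s (one per modality).
#' @param effective_brain brain [label_mask()], already excluding the
#'   stroke lesion when input-masking is active.
#' @param cfg a [feature_config()].
#' @return An object of class `feature_matrix`: `x` (numeric matrix),
#'   `voxel_index` (linear voxel indices of the rows), `fingerprint`.
#' @export
extract_features <- function(volumes, effective_brain, cfg) {
  for (m in cfg$modalities)
    if (is.null(volumes[[m]]))
      stop("missing modality volume: ", m, call. = FALSE)
  inb <- which(effective_brain$data == 1L)
  maskarr <- array(as.numeric(effective_brain$data), dim(effective_brain$data))
  dims <- dim(effective_brain$data)

  cols <- list()
  for (m in cfg$modalities) {
    check_same_grid(volumes[[m]], effective_brain)
    nv <- normalize_intensities(volumes[[m]], effective_brain,
                                cfg$intensity_normalization)
    cols[[m]] <- nv$data[inb]
    if (cfg$patch_size > 0) {
      hw <- patch_halfwidths(cfg$patch_size)
      num <- cpp_box_sum(as.numeric(nv$data) * as.numeric(maskarr), dims,
                         hw["lo"], hw["hi"])
      den <- cpp_box_sum(as.numeric(maskarr), dims, hw["lo"], hw["hi"])
      cols[[paste0(m, "_patch")]] <- num[inb] / den[inb]
    }
  }
  if (cfg$spatial_weighting > 0) {
    w <- grid_world_coords(effective_brain)[inb, , drop = FALSE]
    ctr_vox <- (dims - 1) / 2
    ctr <- as.vector(effective_brain$affine %*% c(ctr_vox, 1))[1:3]
    half_extent <- max(dims * effective_brain$voxel_size) / 2
    sp <- sweep(w, 2, ctr) / half_extent * cfg$spatial_weighting
    cols$x <- sp[, 1]; cols$y <- sp[, 2]; cols$z <- sp[, 3]
  }
  # order: intensities, then patches, then spatial
  nm <- c(cfg$modalities,
          if (cfg$patch_size > 0) paste0(cfg$modalities, "_patch"),
          if (cfg$spatial_weighting > 0) c("x", "y", "z"))
  x <- do.call(cbind, cols[nm])
  colnames(x) <- nm
  fp <- paste(c(nm, cfg$intensity_normalization, cfg$patch_size,
                cfg$spatial_weighting), collapse = "|")
  structure(list(x = x, voxel_index = inb, fingerprint = fp, dims = dims),
            class = "feature_matrix")
}

#' Sample lesion and non-lesion training voxels
#'
#' Lesion points are drawn uniformly without replacement from the gold WMH
#' mask (`"ALL"` takes every gold voxel). The non-lesion candidate pool
#' depends on `location`: `any` = effective brain minus gold; `noborder`
#' additionally removes the 1-voxel 26-neighbourhood border of the gold
#' mask; `surround` is exactly that border (inside the effective brain).
#' Requests larger than a pool draw the whole pool and record a warning.
#'
#' @param gold gold-standard WMH [label_mask()].
#' @param effective_brain brain mask with stroke removed when input-masking.
#' @param cfg a [sampling_config()].
#' @return List with `lesion` and `nonlesion` (sorted linear voxel
#'   indices, disjoint) and `warnings` (character).
#' @export
sample_training_points <- function(gold, effective_brain, cfg) {
  check_same_grid(gold, effective_brain)
  eff <- effective_brain$data == 1L
  g <- gold$data == 1L & eff
  lesion_pool <- which(g)
  border <- dilate_voxel26(label_mask(array(as.integer(g), dim(gold$data)),
                                      gold$voxel_size, gold$affine,
                                      "WMH_GOLD"))$data == 1L
  nonlesion_pool <- switch(cfg$location,
    any = which(eff & !g),
    noborder = which(eff & !border),
    surround = which(eff & border & !g))

  warnings <- character()
  draw <- function(pool, n, what) {
    if (identical(n, "ALL")) return(sort(pool))
    if (n >= length(pool)) {
      if (n > length(pool))
        warnings <<- c(warnings, sprintf(
          "requested %d %s points but pool has only %d; using all",
          n, what, length(pool)))
      return(sort(pool))
    }
    sort(sample(pool, n))
  }
  with_seed(cfg$seed, {
    lesion <- draw(lesion_pool, cfg$n_lesion, "lesion")
    n_non <- if (identical(cfg$n_nonlesion, "EQUAL")) length(lesion)
             else cfg$n_nonlesion
    nonlesion <- draw(nonlesion_pool, n_non, "non-lesion")
  })
  list(lesion = lesion, nonlesion = nonlesion, warnings = warnings)
}
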