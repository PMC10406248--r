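# Synthetic multi-site, multi-modal brain phantoms with ground-truth WMH,
# stroke, brain and ventricle masks. The phantom is deliberately minimal:
# an ellipsoidal head, two ellipsoidal lateral ventricles, spherical-blob
# WMH clusters with a periventricular placement bias, and an optional
# spherical stroke lesion whose intensity mimics WMH. That is the smallest
# structure that exercises intensity features, spatial weighting,
# periventricular vs. deep clusters, and stroke-vs-WMH confusability.

#' Tissue intensity model for phantom generation
#'
#' Class-conditional mean intensities (arbitrary units) per modality for the
#' five phantom tissue classes, plus per-modality noise and an optional
#' isotropic Gaussian smoothing. Defaults encode the standard contrasts:
#' WMH and stroke are FLAIR-hyperintense relative to parenchyma, CSF is
#' dark on T1 and FLAIR, bright on T2. The stroke lesion defaults to the
#' WMH means in every modality (maximal confusability), so experiments on
#' stroke handling have signal.
#'
#' @param means named list per modality of named numeric vectors with
#'   entries `background`, `parenchyma`, `csf`, `wmh`, `stroke`.
#' @param noise_sd named numeric vector of Gaussian noise SD per modality.
#' @param smoothing_fwhm_mm isotropic Gaussian smoothing FWHM in mm applied
#'   to the final images (0 = none, the default, keeping class means exact).
#' @return An object of class `tissue_model`.
#' @export
tissue_model <- function(
    means = list(
      FLAIR = c(background = 0, parenchyma = 100, csf = 50, wmh = 140, stroke = 140),
      T1    = c(background = 0, parenchyma = 100, csf = 40, wmh = 100, stroke = 100),
      T2    = c(background = 0, parenchyma = 100, csf = 180, wmh = 140, stroke = 140)),
    noise_sd = c(FLAIR = 10, T1 = 10, T2 = 10),
    smoothing_fwhm_mm = 0) {
  cls <- c("background", "parenchyma", "csf", "wmh", "stroke")
  for (m in names(means)) {
    if (!all(cls %in% names(means[[m]])))
      stop("tissue means for ", m, " must name all five classes", call. = FALSE)
  }
  if (!"FLAIR" %in% names(means))
    stop("a FLAIR tissue model is required", call. = FALSE)
  if (means$FLAIR["wmh"] <= means$FLAIR["parenchyma"])
    stop("WMH must be FLAIR-hyperintense relative to parenchyma", call. = FALSE)
  if (!is.null(means$T1) && means$T1["csf"] >= means$T1["parenchyma"])
    stop("CSF must be darker than parenchyma on T1", call. = FALSE)
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(means = means, noise_sd = noise_sd,
                 smoothing_fwhm_mm = smoothing_fwhm_mm),
            class = "tissue_model")
}

#' Acquisition-site effect
#'
#' A linear intensity transform plus a noise multiplier emulating systematic
#' scanner/protocol differences between acquisition sites: `v -> gain * v +
#' offset`, noise SD scaled by `noise_scale`. The identity site is
#' `(1, 0, 1)`.
#'
#' @param gain multiplicative factor, scalar or named per modality (> 0).
#' @param offset additive shift, scalar or named per modality.
#' @param noise_scale multiplier on the tissue model's noise SD (> 0).
#' @return An object of class `site_effect`.
#' @export
site_effect <- function(gain = 1, offset = 0, noise_scale = 1) {
  if (any(gain <= 0)) stop("gain must be > 0", call. = FALSE)
  if (any(noise_scale <= 0)) stop("noise_scale must be > 0", call. = FALSE)
  structure(list(gain = gain, offset = offset, noise_scale = noise_scale),
            class = "site_effect")
}

site_param <- function(p, modality) {
  if (is.null(names(p))) p[[1]] else unname(p[[modality]])
}

#' Phantom lesion and anatomy geometry
#'
#' Grid, head/ventricle ellipsoids, WMH cluster counts/sizes with a
#' periventricular placement bias, and the optional stroke lesion.
#'
#' @param shape grid dimensions (voxels).
#' @param voxel_size voxel size in mm.
#' @param brain_axes_mm semi-axes of the head ellipsoid (mm).
#' @param ventricle_axes_mm semi-axes of each lateral-ventricle ellipsoid (mm).
#' @param ventricle_sep_mm lateral offset of each ventricle from midline (mm).
#' @param n_wmh_clusters number of WMH clusters; a length-2 vector is a
#'   range sampled uniformly per subject.
#' @param wmh_radius_range_mm min/max WMH blob radius (mm).
#' @param periventricular_fraction probability that a WMH cluster seed lies
#'   within `d_pv` mm of the ventricles.
#' @param d_pv periventricular distance cutoff (mm).
#' @param stroke_present logical; place a stroke lesion?
#' @param stroke_radius_mm stroke blob radius (mm).
#' @return An object of class `lesion_geometry`.
#' @export
lesion_geometry <- function(shape = c(64, 64, 64), voxel_size = c(1, 1, 1),
                            brain_axes_mm = c(26, 30, 24),
                            ventricle_axes_mm = c(3.5, 10, 6),
                            ventricle_sep_mm = 7,
                            n_wmh_clusters = c(10, 20),
                            wmh_radius_range_mm = c(1.5, 4.5),
                            periventricular_fraction = 0.7, d_pv = 10,
                            stroke_present = TRUE, stroke_radius_mm = 10) {
  stopifnot(length(shape) == 3, all(shape >= 1), all(voxel_size > 0),
            periventricular_fraction >= 0, periventricular_fraction <= 1,
            d_pv > 0, stroke_radius_mm > 0,
            wmh_radius_range_mm[1] <= wmh_radius_range_mm[2])
  structure(list(shape = as.integer(shape), voxel_size = voxel_size,
                 brain_axes_mm = brain_axes_mm,
                 ventricle_axes_mm = ventricle_axes_mm,
                 ventricle_sep_mm = ventricle_sep_mm,
                 n_wmh_clusters = n_wmh_clusters,
                 wmh_radius_range_mm = wmh_radius_range_mm,
                 periventricular_fraction = periventricular_fraction,
                 d_pv = d_pv, stroke_present = stroke_present,
                 stroke_radius_mm = stroke_radius_mm),
            class = "lesion_geometry")
}

# mm coordinates of voxel centres relative to the grid centre, per axis
grid_mm_axes <- function(geom) {
  lapply(1:3, function(a) {
    (seq_len(geom$shape[a]) - 1 - (geom$shape[a] - 1) / 2) * geom$voxel_size[a]
  })
}

ellipsoid_mask <- function(geom, center_mm, axes_mm) {
  ax <- grid_mm_axes(geom)
  u <- (ax[[1]] - center_mm[1]) / axes_mm[1]
  v <- (ax[[2]] - center_mm[2]) / axes_mm[2]
  w <- (ax[[3]] - center_mm[3]) / axes_mm[3]
  q <- outer(outer(u^2, v^2, `+`), w^2, `+`)
  array(as.integer(q <= 1), geom$shape)
}

sphere_voxels <- function(geom, center_mm, radius_mm) {
  ax <- grid_mm_axes(geom)
  u <- (ax[[1]] - center_mm[1])^2
  v <- (ax[[2]] - center_mm[2])^2
  w <- (ax[[3]] - center_mm[3])^2
  q <- outer(outer(u, v, `+`), w, `+`)
  which(q <= radius_mm^2)
}

separable_gaussian_smooth <- function(arr, fwhm_mm, voxel_size) {
  sig <- fwhm_mm / 2.3548
  for (a in 1:3) {
    s <- sig / voxel_size[a]
    if (s <= 0) next
    n <- dim(arr)[a]
    K <- outer(seq_len(n), seq_len(n),
               function(i, j) exp(-(i - j)^2 / (2 * s^2)))
    K <- K / rowSums(K)
    arr <- apply(arr, setdiff(1:3, a), function(line) as.vector(K %*% line))
    arr <- aperm(arr, order(c(a, setdiff(1:3, a))))
  }
  arr
}

#' Generate one phantom subject
#'
#' Deterministic given `seed`: builds brain/ventricle/stroke/WMH masks
#' satisfying the disjointness invariants (WMH, stroke and ventricles are
#' pairwise disjoint; all masks lie inside the brain), then renders each
#' modality as `gain * class_mean + offset + N(0, noise_scale * noise_sd)`,
#' optionally smoothed.
#'
#' @param tissue a [tissue_model()].
#' @param geom a [lesion_geometry()].
#' @param site a [site_effect()].
#' @param seed integer RNG seed.
#' @param subject_id,site_id identifiers stored with the subject.
#' @return An object of class `phantom_subject`: named `volumes`
#'   ([volume3d()] per modality) and `masks` (`WMH_GOLD`, `STROKE`, `BRAIN`,
#'   `VENTRICLE` [label_mask()]s), plus ids and the seed.
#' @export
generate_subject <- function(tissue, geom, site = site_effect(), seed = 1,
                             subject_id = sprintf("subj%04d", seed),
                             site_id = "siteA") {
  vs <- geom$voxel_size
  aff <- diag(c(vs, 1))
  with_seed(seed, {
    brain <- ellipsoid_mask(geom, c(0, 0, 0), geom$brain_axes_mm)
    vent <- ellipsoid_mask(geom, c(-geom$ventricle_sep_mm, 0, 2),
                           geom$ventricle_axes_mm) |
      ellipsoid_mask(geom, c(geom$ventricle_sep_mm, 0, 2),
                     geom$ventricle_axes_mm)
    vent <- array(as.integer(vent & brain), geom$shape)

    vent_mask <- label_mask(vent, vs, aff, "VENTRICLE")
    vdist <- distance_to_mask(vent_mask)$data

    brain_idx <- which(brain == 1L & vent == 0L)

    # stroke: deep, clear of the ventricles
    stroke <- array(0L, geom$shape)
    if (geom$stroke_present) {
      pool <- brain_idx[vdist[brain_idx] > geom$stroke_radius_mm + 1]
      placed <- FALSE
      for (att in seq_len(1000)) {
        ctr <- arrayInd(sample(pool, 1), geom$shape)
        ctr_mm <- (ctr - 1 - (geom$shape - 1) / 2) * vs
        vox <- sphere_voxels(geom, ctr_mm, geom$stroke_radius_mm)
        vox <- vox[brain[vox] == 1L]
        if (length(vox) && !any(vent[vox] == 1L)) {
          stroke[vox] <- 1L; placed <- TRUE; break
        }
      }
      if (!placed) stop("phantom generation error: could not place stroke",
                        call. = FALSE)
    }

    # WMH clusters with periventricular bias
    nw <- geom$n_wmh_clusters
    n_clust <- if (length(nw) == 2) sample(seq(nw[1], nw[2]), 1) else nw
    pv_pool <- brain_idx[vdist[brain_idx] <= geom$d_pv & vdist[brain_idx] > 0]
    deep_pool <- brain_idx[vdist[brain_idx] > geom$d_pv]
    wmh <- array(0L, geom$shape)
    pv_flags <- logical(n_clust)
    seed_idx <- integer(n_clust)
    for (cl in seq_len(n_clust)) {
      placed <- FALSE
      for (att in seq_len(1000)) {
        pv <- runif(1) < geom$periventricular_fraction
        pool <- if (pv) pv_pool else deep_pool
        ctr <- arrayInd(sample(pool, 1), geom$shape)
        ctr_mm <- (ctr - 1 - (geom$shape - 1) / 2) * vs
        r <- runif(1, geom$wmh_radius_range_mm[1], geom$wmh_radius_range_mm[2])
        vox <- sphere_voxels(geom, ctr_mm, r)
        vox <- vox[brain[vox] == 1L]
        if (length(vox) && !any(vent[vox] == 1L) && !any(stroke[vox] == 1L)) {
          wmh[vox] <- 1L
          pv_flags[cl] <- pv
          seed_idx[cl] <- (ctr[1] - 1) + geom$shape[1] *
            ((ctr[2] - 1) + geom$shape[2] * (ctr[3] - 1)) + 1
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("phantom generation error: could not place WMH cluster",
                        call. = FALSE)
    }

    # render modalities
    vols <- list()
    for (m in names(tissue$means)) {
      mu <- tissue$means[[m]]
      base <- array(mu["background"], geom$shape)
      base[brain == 1L] <- mu["parenchyma"]
      base[vent == 1L] <- mu["csf"]
      base[wmh == 1L] <- mu["wmh"]
      base[stroke == 1L] <- mu["stroke"]
      g <- site_param(site$gain, m)
      o <- site_param(site$offset, m)
      img <- g * base + o
      sdm <- site$noise_scale * unname(tissue$noise_sd[m])
      if (is.na(sdm)) sdm <- 0
      if (sdm > 0) img <- img + array(rnorm(length(img), 0, sdm), geom$shape)
      if (tissue$smoothing_fwhm_mm > 0)
        img <- separable_gaussian_smooth(img, tissue$smoothing_fwhm_mm, vs)
      vols[[m]] <- volume3d(img, vs, aff, m)
    }

    structure(list(
      volumes = vols,
      masks = list(
        WMH_GOLD = label_mask(wmh, vs, aff, "WMH_GOLD"),
        STROKE = label_mask(stroke, vs, aff, "STROKE"),
        BRAIN = label_mask(brain, vs, aff, "BRAIN"),
        VENTRICLE = vent_mask),
      wmh_seed_info = list(voxel_index = seed_idx, periventricular = pv_flags,
                           vent_distance_mm = vdist[seed_idx]),
      subject_id = subject_id, site_id = site_id, seed = seed),
      class = "phantom_subject")
  })
}

#' @export
print.phantom_subject <- function(x, ...) {
  cat(sprintf("<phantom_subject %s (%s, seed %d): %s voxels, WMH %d, stroke %d>\n",
              x$subject_id, x$site_id, x$seed,
              paste(dim(x$volumes[[1]]$data), collapse = "x"),
              sum(x$masks$WMH_GOLD$data), sum(x$masks$STROKE$data)))
  invisible(x)
}

#' Generate a phantom cohort
#'
#' Subjects use consecutive seeds `base_seed .. base_seed + n - 1`; lesion
#' count (and blob sizes) vary per subject within the geometry's stated
#' ranges through each subject's own seed. No hidden global RNG state.
#'
#' @param n number of subjects (>= 1).
#' @inheritParams generate_subject
#' @param base_seed seed of the first subject.
#' @param site_id site label stored on every subject.
#' @return List of [generate_subject()] results.
#' @export
generate_cohort <- function(n, tissue = tissue_model(),
                            geom = lesion_geometry(),
                            site = site_effect(), base_seed = 1,
                            site_id = "siteA") {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  lapply(seq_len(n), function(i) {
    s <- base_seed + i - 1
    generate_subject(tissue, geom, site, seed = s,
                     subject_id = sprintf("%s_subj%04d", site_id, s),
                     site_id = site_id)
  })
}

#' Write a phantom subject as NIfTI files
#'
#' @param subject a `phantom_subject`.
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (m in names(subject$volumes)) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", subject$subject_id, m))
    write_volume(subject$volumes[[m]], p)
    paths[m] <- p
  }
  for (r in names(subject$masks)) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", subject$subject_id, r))
    write_volume(subject$masks[[r]], p)
    paths[r] <- p
  }
  invisible(paths)
}

#' Write a cohort with a CSV manifest
#'
#' @param cohort list of `phantom_subject`s.
#' @param dir output directory.
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  rows <- lapply(cohort, function(s) {
    paths <- write_subject(s, dir)
    data.frame(subject_id = s$subject_id, site_id = s$site_id, seed = s$seed,
               t(paths), stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mf <- file.path(dir, "manifest.csv")
  write.csv(manifest, mf, row.names = FALSE)
  invisible(mf)
}

#' Save or load a phantom configuration as JSON
#'
#' Serializes the tissue model, geometry and site effect driving a phantom
#' cohort, so a generation run is fully described by one small file.
#'
#' @param tissue a [tissue_model()].
#' @param geom a [lesion_geometry()].
#' @param site a [site_effect()].
#' @param path JSON file path.
#' @return `path` invisibly / a list with `tissue`, `geom`, `site`.
#' @export
write_phantom_config <- function(tissue, geom, site, path) {
  jsonlite::write_json(
    list(tissue = list(means = lapply(tissue$means, as.list),
                       noise_sd = as.list(tissue$noise_sd),
                       smoothing_fwhm_mm = tissue$smoothing_fwhm_mm),
         geom = unclass(geom),
         site = list(gain = as.list(site$gain),
                     offset = as.list(site$offset),
                     noise_scale = as.list(site$noise_scale))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tis <- tissue_model(means = lapply(x$tissue$means, unlist),
                      noise_sd = unlist(x$tissue$noise_sd),
                      smoothing_fwhm_mm = x$tissue$smoothing_fwhm_mm)
  geom <- do.call(lesion_geometry, x$geom)
  site <- site_effect(unlist(x$site$gain), unlist(x$site$offset),
                      unlist(x$site$noise_scale))
  list(tissue = tis, geom = geom, site = site)
}

#' Read a cohort from a manifest CSV
#'
#' @param manifest path to a CSV written by [write_cohort()].
#' @return List of `phantom_subject`-shaped lists (volumes + masks + ids).
#' @export
read_cohort <- function(manifest) {
  df <- read.csv(manifest, stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    resolve <- function(p) if (file.exists(p)) p else file.path(dir, basename(p))
    vols <- list()
    for (m in intersect(MODALITIES, names(row)))
      vols[[m]] <- read_volume(resolve(row[[m]]), m)
    masks <- list()
    for (r in intersect(MASK_ROLES, names(row)))
      masks[[r]] <- read_mask(resolve(row[[r]]), r)
    structure(list(volumes = vols, masks = masks,
                   subject_id = row$subject_id, site_id = row$site_id,
                   seed = row$seed),
              class = "phantom_subject")
  })
}
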