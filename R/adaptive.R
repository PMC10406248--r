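# Spatially adaptive thresholding of WMH probability maps — a simplified,
# clearly-labelled surrogate of LOCATE. True LOCATE learns local thresholds
# by regression on local features; this surrogate reduces "location" to
# distance-from-ventricle bands and learns one threshold per band from
# training subjects. It exists to compare fixed vs. spatially adaptive
# thresholding, not to reproduce the original algorithm.

#' Distance-band thresholds
#'
#' @param edges internal band edges in mm (ascending); bands are
#'   `[0, e1], (e1, e2], ..., (e_last, Inf)`. A voxel exactly on an edge
#'   belongs to the lower (ventricle-closer) band.
#' @param taus one threshold in (0, 1) per band (`length(edges) + 1`).
#' @return An object of class `band_thresholds`.
#' @export
band_thresholds <- function(edges, taus) {
  edges <- as.numeric(edges)
  if (length(edges) && (any(diff(edges) <= 0) || any(edges <= 0)))
    stop("band edges must be positive and strictly increasing", call. = FALSE)
  if (length(taus) != length(edges) + 1L)
    stop("need one threshold per band", call. = FALSE)
  if (any(taus <= 0 | taus >= 1)) stop("thresholds must be in (0,1)", call. = FALSE)
  structure(list(edges = edges, taus = as.numeric(taus)),
            class = "band_thresholds")
}

band_index <- function(dist_mm, edges) {
  if (!length(edges)) return(rep.int(1L, length(dist_mm)))
  1L + rowSums(outer(dist_mm, edges, `>`))
}

#' Learn per-band thresholds from training subjects
#'
#' For every distance band (distance from the ventricle mask) the threshold
#' is the candidate-grid value maximizing the mean within-band Dice across
#' the training subjects; ties pick the largest (most conservative)
#' threshold. A band containing no gold voxels in any training subject gets
#' the maximum grid value, with a warning recorded.
#'
#' @param probs list of probability [volume3d()]s (one per subject).
#' @param golds list of gold WMH [label_mask()]s.
#' @param ventricles list of ventricle [label_mask()]s.
#' @param grid candidate thresholds.
#' @param edges internal band edges in mm; default a single 10 mm
#'   periventricular/deep cutoff. `edges = numeric(0)` reduces the fit to
#'   a global fixed-threshold search.
#' @return A [band_thresholds()] with attribute `"warnings"`.
#' @export
fit_band_thresholds <- function(probs, golds, ventricles,
                                grid = c(seq(0.5, 0.95, by = 0.05), 0.99),
                                edges = 10) {
  stopifnot(length(probs) >= 1, length(probs) == length(golds),
            length(probs) == length(ventricles))
  edges <- as.numeric(edges)
  nb <- length(edges) + 1L
  grid <- sort(grid)
  # per subject: band index and vectors needed for the band-Dice
  subj <- lapply(seq_along(probs), function(i) {
    if (sum(ventricles[[i]]$data) == 0L)
      stop("ventricle mask is empty", call. = FALSE)
    d <- distance_to_mask(ventricles[[i]])$data
    list(band = band_index(as.vector(d), edges),
         p = as.vector(probs[[i]]$data),
         g = as.vector(golds[[i]]$data) == 1)
  })
  warnings <- character()
  taus <- numeric(nb)
  for (b in seq_len(nb)) {
    has_gold <- vapply(subj, function(s) any(s$g[s$band == b]), logical(1))
    if (!any(has_gold)) {
      taus[b] <- max(grid)
      warnings <- c(warnings, sprintf(
        "band %d has no gold voxels in any training subject; using max grid value", b))
      next
    }
    mean_dice <- vapply(grid, function(tau) {
      d <- vapply(subj, function(s) {
        inb <- s$band == b
        g <- s$g[inb]
        if (!any(g)) return(NA_real_)
        a <- s$p[inb] >= tau
        2 * sum(a & g) / (sum(a) + sum(g))
      }, numeric(1))
      mean(d, na.rm = TRUE)
    }, numeric(1))
    # ties -> largest tau (grid is sorted ascending)
    taus[b] <- grid[max(which(mean_dice >= max(mean_dice) - 1e-12))]
  }
  structure(band_thresholds(edges, taus), warnings = warnings)
}

#' Save or load band thresholds as JSON
#'
#' @param bt a [band_thresholds()].
#' @param path JSON file path.
#' @return `path` invisibly / the restored [band_thresholds()].
#' @export
write_band_thresholds <- function(bt, path) {
  jsonlite::write_json(list(edges = bt$edges, taus = bt$taus), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_band_thresholds
#' @export
read_band_thresholds <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  band_thresholds(x$edges, x$taus)
}

#' Apply distance-band thresholds to a probability map
#'
#' Each voxel is assigned to the band containing its distance from the
#' ventricles and binarized at that band's threshold (`p >= tau_band`).
#' With a single band this is bitwise-identical to [binarize()].
#'
#' @param prob probability [volume3d()].
#' @param ventricle ventricle [label_mask()] on the same grid.
#' @param bt a [band_thresholds()].
#' @return A [label_mask()] with role `WMH_AUTO`.
#' @export
apply_band_thresholds <- function(prob, ventricle, bt) {
  check_same_grid(prob, ventricle)
  d <- distance_to_mask(ventricle)$data
  band <- band_index(as.vector(d), bt$edges)
  m <- as.integer(as.vector(prob$data) >= bt$taus[band])
  label_mask(array(m, dim(prob$data)), prob$voxel_size, prob$affine,
             "WMH_AUTO")
}
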