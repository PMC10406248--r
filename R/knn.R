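# Supervised WMH segmentation: exact k-NN class-probability estimation over
# labelled training feature vectors, fixed-threshold binarization, and
# stroke-lesion handling on classifier input or output.

#' Segmentation settings
#'
#' The full user-settings space of the supervised segmenter: the feature
#' space, the training-point sampling policy, the neighbour count `k`, the
#' probability threshold, and how the stroke lesion is handled —
#' `"mask_input"` removes stroke voxels from the brain mask before feature
#' extraction and training; `"mask_output"` predicts over the full brain and
#' afterwards deletes the (optionally dilated) stroke mask from the output.
#'
#' @param feature_config a [feature_config()].
#' @param sampling_config a [sampling_config()].
#' @param k number of neighbours (default 40).
#' @param tau probability threshold in (0, 1); the tested grid is
#'   `{0.8, 0.85, 0.9, 0.95, 0.99}` with 0.85 the recommended fixed value.
#' @param stroke_mode `"mask_input"` or `"mask_output"`.
#' @param output_dilation_mm dilation (mm) applied to the stroke mask
#'   before removal from the output (output masking only).
#' @return An object of class `segmentation_settings`.
#' @export
segmentation_settings <- function(feature_config = strokewmh::feature_config(),
                                  sampling_config = strokewmh::sampling_config(),
                                  k = 40, tau = 0.85,
                                  stroke_mode = c("mask_input", "mask_output"),
                                  output_dilation_mm = 0) {
  stroke_mode <- match.arg(stroke_mode)
  if (tau <= 0 || tau >= 1) stop("tau must be in (0,1)", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (output_dilation_mm < 0)
    stop("output_dilation_mm must be >= 0", call. = FALSE)
  structure(list(feature_config = feature_config,
                 sampling_config = sampling_config, k = as.integer(k),
                 tau = tau, stroke_mode = stroke_mode,
                 output_dilation_mm = output_dilation_mm),
            class = "segmentation_settings")
}

# brain mask with stroke removed when input-masking is active
effective_brain_mask <- function(subject, settings) {
  brain <- subject$masks$BRAIN
  stroke <- subject$masks$STROKE
  if (is.null(stroke))
    stop("configuration error: stroke handling requested but subject has no stroke mask",
         call. = FALSE)
  if (settings$stroke_mode == "mask_input" && sum(stroke$data) > 0) {
    d <- array(as.integer(brain$data == 1L & stroke$data == 0L),
               dim(brain$data))
    return(label_mask(d, brain$voxel_size, brain$affine, "BRAIN"))
  }
  brain
}

#' Fit the supervised k-NN WMH segmenter
#'
#' Samples labelled lesion / non-lesion feature vectors from each training
#' subject (per the sampling policy; per-subject seeds are
#' `sampling_config$seed + subject position - 1`) and stores them with `k`.
#' Under `"mask_input"` stroke voxels are excluded from both the feature
#' domain and the sampling pools.
#'
#' @param subjects list of training subjects (e.g. from
#'   [generate_cohort()]); each needs `volumes` and masks `BRAIN`,
#'   `WMH_GOLD`, `STROKE`.
#' @param settings a [segmentation_settings()].
#' @return An object of class `wmh_knn`: training matrix, 0/1 labels, `k`,
#'   feature fingerprint, settings and provenance. Methods: [print.wmh_knn()],
#'   [summary.wmh_knn()], [predict.wmh_knn()].
#' @export
wmh_knn <- function(subjects, settings = segmentation_settings()) {
  if (!length(subjects)) stop("need at least one training subject", call. = FALSE)
  rows <- list(); labs <- list(); prov <- list(); fp <- NULL
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    if (is.null(s$masks$WMH_GOLD))
      stop("training subject ", i, " lacks a gold WMH mask", call. = FALSE)
    eff <- effective_brain_mask(s, settings)
    fm <- extract_features(s$volumes, eff, settings$feature_config)
    fp <- fm$fingerprint
    scfg <- settings$sampling_config
    scfg$seed <- scfg$seed + i - 1L
    pts <- sample_training_points(s$masks$WMH_GOLD, eff, scfg)
    ri <- match(c(pts$lesion, pts$nonlesion), fm$voxel_index)
    rows[[i]] <- fm$x[ri, , drop = FALSE]
    labs[[i]] <- rep(c(1L, 0L), c(length(pts$lesion), length(pts$nonlesion)))
    prov[[i]] <- list(subject_id = s$subject_id, seed = scfg$seed,
                      n_lesion = length(pts$lesion),
                      n_nonlesion = length(pts$nonlesion),
                      warnings = pts$warnings)
  }
  x <- do.call(rbind, rows)
  y <- unlist(labs)
  if (sum(y) == 0L)
    stop("unfit model: no lesion voxels in the training cohort", call. = FALSE)
  if (settings$k > nrow(x))
    stop("k exceeds the number of training rows", call. = FALSE)
  structure(list(x = x, y = y, k = settings$k, fingerprint = fp,
                 settings = settings, provenance = prov),
            class = "wmh_knn")
}

#' @export
print.wmh_knn <- function(x, ...) {
  cat(sprintf("<wmh_knn: %d training rows (%d lesion / %d non-lesion), k = %d>\n",
              nrow(x$x), sum(x$y), sum(1 - x$y), x$k))
  cat("  features:", paste(colnames(x$x), collapse = ", "), "\n")
  cat("  stroke handling:", x$settings$stroke_mode,
      " threshold:", x$settings$tau, "\n")
  invisible(x)
}

#' @export
#' @method summary wmh_knn
summary.wmh_knn <- function(object, ...) {
  print(object)
  prov <- do.call(rbind, lapply(object$provenance, function(p)
    data.frame(subject_id = p$subject_id, seed = p$seed,
               n_lesion = p$n_lesion, n_nonlesion = p$n_nonlesion)))
  print(prov, row.names = FALSE)
  invisible(prov)
}

#' Predict the WMH probability map for a subject
#'
#' Exact k-NN: each in-brain voxel's probability is the proportion of WMH
#' labels among its `k` nearest training vectors (Euclidean distance, ties
#' broken by lower training-row index); values are exact multiples of
#' `1/k` and 0 outside the effective brain.
#'
#' @param object a fitted [wmh_knn()] model.
#' @param subject the subject to segment.
#' @param type `"prob"` for the probability [volume3d()], `"mask"` for the
#'   thresholded [label_mask()].
#' @param settings optional [segmentation_settings()] override (e.g. a
#'   different threshold or stroke mode); feature settings must match the
#'   model fingerprint.
#' @param ... unused.
#' @return A [volume3d()] (`type = "prob"`) or [label_mask()]
#'   (`type = "mask"`).
#' @export
predict.wmh_knn <- function(object, subject, type = c("prob", "mask"),
                            settings = object$settings, ...) {
  type <- match.arg(type)
  seg <- segment_subject(object, subject, settings)
  if (type == "prob") seg$prob else seg$mask
}

#' Binarize a probability map
#'
#' `mask = (p >= tau)`; the comparison is inclusive.
#'
#' @param prob probability [volume3d()].
#' @param tau threshold in (0, 1).
#' @return A [label_mask()] with role `WMH_AUTO`.
#' @export
binarize <- function(prob, tau) {
  if (tau <= 0 || tau >= 1) stop("tau must be in (0,1)", call. = FALSE)
  label_mask(array(as.integer(prob$data >= tau), dim(prob$data)),
             prob$voxel_size, prob$affine, "WMH_AUTO")
}

#' Segment a subject with a fitted k-NN model
#'
#' Runs feature extraction under the configured stroke handling, predicts
#' the probability map, thresholds it, and removes the (dilated) stroke
#' mask from the output under `"mask_output"`. In both modes the final
#' mask never intersects the stroke mask.
#'
#' @inheritParams predict.wmh_knn
#' @return List with `prob` ([volume3d()], modality `PROB`) and `mask`
#'   ([label_mask()], role `WMH_AUTO`).
#' @export
segment_subject <- function(object, subject, settings = object$settings) {
  for (m in object$settings$feature_config$modalities)
    if (is.null(subject$volumes[[m]]))
      stop("subject lacks modality required by the model: ", m, call. = FALSE)
  eff <- effective_brain_mask(subject, settings)
  fm <- extract_features(subject$volumes, eff, settings$feature_config)
  if (!identical(fm$fingerprint, object$fingerprint))
    stop("feature mismatch: query feature layout differs from the model",
         call. = FALSE)
  p <- cpp_knn_prob(object$x, object$y, fm$x, object$k)
  parr <- array(0, dim(eff$data))
  parr[fm$voxel_index] <- p
  g <- subject$volumes[[1]]
  prob <- volume3d(parr, g$voxel_size, g$affine, "PROB")

  stroke <- subject$masks$STROKE
  if (settings$stroke_mode == "mask_output" && sum(stroke$data) > 0) {
    dil <- dilate_mask(stroke, settings$output_dilation_mm)
    prob$data[dil$data == 1L] <- 0
  }
  mask <- binarize(prob, settings$tau)
  # contract: output never intersects the stroke lesion, either mode
  mask$data[stroke$data == 1L] <- 0L
  list(prob = prob, mask = mask)
}
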