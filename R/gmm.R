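# Unsupervised multimodal lesion segmentation: a diagonal-covariance
# Gaussian mixture over in-brain intensity vectors fitted by EM, with the
# lesion class identified as the component with the highest FLAIR mean and
# the stroke lesion removed from the output mask (post-processing only).
# This is an intensity-clustering baseline in the spirit of generative
# whole-brain segmenters, without atlas deformation or shape priors.

#' Fit a Gaussian mixture to intensity vectors
#'
#' Diagonal-covariance EM with k-means initialization from `seed`. The
#' log-likelihood is non-decreasing across iterations; collapsing
#' components are caught by a variance floor (`var_floor_frac` times the
#' per-dimension data variance) with a warning.
#'
#' @param x numeric matrix (rows = voxels, columns = modalities) or vector.
#' @param K number of mixture components (default 4: CSF, parenchyma split
#'   over two components, and a hyperintense lesion-like class).
#' @param max_iters,tol EM stopping rule (relative log-likelihood change).
#' @param seed RNG seed for the k-means initialization.
#' @param var_floor_frac variance floor as a fraction of the data variance.
#' @return List with `means` (K x d), `vars` (K x d), `weights`,
#'   `resp` (n x K responsibilities, rows sum to 1), `loglik` (trace),
#'   `converged`, `floored`.
#' @export
fit_gmm <- function(x, K = 4, max_iters = 100, tol = 1e-6, seed = 1,
                    var_floor_frac = 1e-6) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n == 0L) stop("no intensity vectors to fit", call. = FALSE)
  if (nrow(unique(x)) < K)
    stop("need at least K distinct intensity vectors", call. = FALSE)

  floor_var <- pmax(apply(x, 2, function(col) var(col)) * var_floor_frac,
                    .Machine$double.eps)

  km <- with_seed(seed, kmeans(x, centers = K, nstart = 5, iter.max = 100,
                               algorithm = "Lloyd"))
  mu <- km$centers
  sg <- matrix(0, K, d)
  w <- as.numeric(table(factor(km$cluster, levels = seq_len(K)))) / n
  for (k in seq_len(K)) {
    xk <- x[km$cluster == k, , drop = FALSE]
    v <- if (nrow(xk) > 1) apply(xk, 2, var) else floor_var
    sg[k, ] <- pmax(v, floor_var)
  }
  w <- pmax(w, 1e-8); w <- w / sum(w)

  loglik <- numeric(0)
  floored <- FALSE
  resp <- NULL
  for (it in seq_len(max_iters)) {
    # E step (log domain)
    lp <- matrix(0, n, K)
    for (k in seq_len(K)) {
      z <- sweep(x, 2, mu[k, ])
      lp[, k] <- log(w[k]) -
        0.5 * (d * log(2 * pi) + sum(log(sg[k, ]))) -
        0.5 * rowSums(sweep(z^2, 2, sg[k, ], `/`))
    }
    m <- apply(lp, 1, max)
    ll <- sum(m + log(rowSums(exp(lp - m))))
    loglik <- c(loglik, ll)
    resp <- exp(lp - m)
    resp <- resp / rowSums(resp)
    if (it > 1 && abs(ll - loglik[it - 1]) <=
        tol * (abs(loglik[it - 1]) + 1e-12)) break
    # M step
    nk <- colSums(resp)
    w <- pmax(nk / n, 1e-12); w <- w / sum(w)
    for (k in seq_len(K)) {
      mu[k, ] <- colSums(resp[, k] * x) / nk[k]
      z <- sweep(x, 2, mu[k, ])
      v <- colSums(resp[, k] * z^2) / nk[k]
      if (any(v < floor_var)) floored <- TRUE
      sg[k, ] <- pmax(v, floor_var)
    }
  }
  if (floored)
    warning("one or more component variances hit the floor", call. = FALSE)
  list(means = mu, vars = sg, weights = w, resp = resp, loglik = loglik,
       converged = length(loglik) < max_iters, floored = floored)
}

#' Fit the unsupervised GMM lesion segmenter to a subject
#'
#' Fits [fit_gmm()] to the subject's in-brain intensity vectors over the
#' requested modalities. Requires no training masks.
#'
#' @param subject subject with `volumes` and a `BRAIN` mask.
#' @param modalities modalities used as intensity dimensions (FLAIR needed
#'   for the default lesion-class rule).
#' @param K,max_iters,tol,seed,var_floor_frac passed to [fit_gmm()].
#' @return An object of class `wmh_gmm` with the fitted mixture, the brain
#'   voxel indices and the modality order. Methods: `print`, `summary`,
#'   `predict` (probability map or thresholded mask).
#' @export
wmh_gmm <- function(subject, modalities = c("FLAIR", "T1"), K = 4,
                    max_iters = 100, tol = 1e-6, seed = 1,
                    var_floor_frac = 1e-6) {
  brain <- subject$masks$BRAIN
  if (is.null(brain) || sum(brain$data) == 0L)
    stop("subject has no (non-empty) brain mask", call. = FALSE)
  for (m in modalities)
    if (is.null(subject$volumes[[m]]))
      stop("missing modality volume: ", m, call. = FALSE)
  inb <- which(brain$data == 1L)
  x <- vapply(modalities, function(m) subject$volumes[[m]]$data[inb],
              numeric(length(inb)))
  fit <- fit_gmm(x, K = K, max_iters = max_iters, tol = tol, seed = seed,
                 var_floor_frac = var_floor_frac)
  structure(list(fit = fit, voxel_index = inb, modalities = modalities,
                 dims = dim(brain$data), voxel_size = brain$voxel_size,
                 affine = brain$affine, K = K, seed = seed),
            class = "wmh_gmm")
}

#' @export
print.wmh_gmm <- function(x, ...) {
  cat(sprintf("<wmh_gmm: %d components over (%s), %d voxels, loglik %.1f%s>\n",
              x$K, paste(x$modalities, collapse = ", "),
              length(x$voxel_index), tail(x$fit$loglik, 1),
              if (x$fit$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
#' @method summary wmh_gmm
summary.wmh_gmm <- function(object, ...) {
  print(object)
  df <- data.frame(component = seq_len(object$K),
                   weight = round(object$fit$weights, 4),
                   round(object$fit$means, 2))
  names(df)[-(1:2)] <- paste0("mean_", object$modalities)
  print(df, row.names = FALSE)
  invisible(df)
}

#' Lesion probability map from a fitted mixture
#'
#' The lesion class is picked by `rule`: `"highest_flair_mean"` (the
#' FLAIR-hyperintense component — WMHs are FLAIR-bright by definition) or a
#' manual component index. The map holds that component's responsibility
#' at each in-brain voxel.
#'
#' @param object a fitted [wmh_gmm()].
#' @param rule `"highest_flair_mean"` or `"manual"`.
#' @param class_index component index when `rule = "manual"`.
#' @return A probability [volume3d()] (modality `PROB`).
#' @export
lesion_probability <- function(object, rule = c("highest_flair_mean", "manual"),
                               class_index = NULL) {
  rule <- match.arg(rule)
  if (rule == "highest_flair_mean") {
    fi <- match("FLAIR", object$modalities)
    if (is.na(fi))
      stop("configuration error: FLAIR not among fitted modalities", call. = FALSE)
    class_index <- which.max(object$fit$means[, fi])
  } else if (is.null(class_index) || class_index < 1 ||
             class_index > object$K) {
    stop("configuration error: invalid manual class index", call. = FALSE)
  }
  parr <- array(0, object$dims)
  parr[object$voxel_index] <- object$fit$resp[, class_index]
  structure(volume3d(parr, object$voxel_size, object$affine, "PROB"),
            lesion_class = class_index)
}

#' @export
predict.wmh_gmm <- function(object, type = c("prob", "mask"), tau = 0.1,
                            stroke = NULL, ...) {
  type <- match.arg(type)
  prob <- lesion_probability(object)
  if (type == "prob") return(prob)
  mask <- binarize(prob, tau)
  if (!is.null(stroke)) mask$data[stroke$data == 1L] <- 0L
  mask
}

#' Unsupervised GMM lesion segmentation of a subject
#'
#' Fits the mixture, thresholds the lesion-class responsibility at `tau`
#' (the studied grid is `{0.1, 0.3, 0.5, 0.7, 0.9}`; 0.1 performed best and
#' is the default) and removes the stroke lesion from the output mask —
#' post-processing removal only, mirroring how unsupervised segmenters are
#' used with stroke data (no input masking).
#'
#' @inheritParams wmh_gmm
#' @param tau posterior probability threshold.
#' @return List with `mask` ([label_mask()]), `prob` ([volume3d()]) and the
#'   fitted `model` ([wmh_gmm()]).
#' @export
segment_unsupervised <- function(subject, modalities = c("FLAIR", "T1"),
                                 K = 4, tau = 0.1, seed = 1, ...) {
  model <- wmh_gmm(subject, modalities = modalities, K = K, seed = seed, ...)
  prob <- lesion_probability(model)
  mask <- binarize(prob, tau)
  stroke <- subject$masks$STROKE
  if (!is.null(stroke)) mask$data[stroke$data == 1L] <- 0L
  list(mask = mask, prob = prob, model = model)
}
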