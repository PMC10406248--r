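# Scoring of automated vs. gold-standard WMH masks. Voxel level: Dice
# similarity (SI), false discovery ratio (FDR), false negative ratio (FNR).
# Cluster level (connected components): FDRc / FNRc, plus the detection /
# outline error-rate split (DER / OER) relative to the mean total volume of
# the two masks. Volume agreement across subjects: ICC(A,1) — two-way
# random effects, absolute agreement, single measure. Metrics that are
# undefined for a subject (empty automated or gold mask) are reported as
# NaN and excluded from cohort means, with counts retained — silently
# scoring them as zero would bias the means.

#' Voxel-level overlap metrics
#'
#' With `TP = |G & A|`, `FP = |A \ G|`, `FN = |G \ A|`:
#' `SI = 2 TP / (2 TP + FP + FN)`, `FDR = FP / |A|`, `FNR = FN / |G|`.
#' An empty automated mask makes FDR undefined (NaN); an empty gold mask
#' makes SI and FNR undefined.
#'
#' @param gold,auto [label_mask()]s on the same grid.
#' @return Named numeric `c(SI, FDR, FNR)` (NaN where undefined).
#' @export
voxel_metrics <- function(gold, auto) {
  check_same_grid(gold, auto)
  g <- gold$data == 1L; a <- auto$data == 1L
  tp <- sum(g & a); fp <- sum(a & !g); fn <- sum(g & !a)
  c(SI = if (sum(g)) 2 * tp / (2 * tp + fp + fn) else NaN,
    FDR = if (sum(a)) fp / sum(a) else NaN,
    FNR = if (sum(g)) fn / sum(g) else NaN)
}

#' Cluster-level overlap metrics
#'
#' Clusters are connected components (26-adjacency by default); a gold and
#' an automated cluster "overlap" if they share at least one voxel. With
#' `MTA = (|G| + |A|) / 2`:
#' `FDRc` = fraction of automated clusters overlapping no gold cluster;
#' `FNRc` = fraction of gold clusters overlapping no automated cluster;
#' `DER` = (voxels of all non-overlapping clusters, gold and automated) / MTA;
#' `OER` = (voxels of overlapping clusters outside the gold-automated
#' intersection) / MTA. `DER + OER = (FP + FN) / MTA` and
#' `SI = 1 - (DER + OER)/2` hold identically.
#'
#' @param gold,auto [label_mask()]s on the same grid.
#' @param connectivity cluster adjacency (6, 18 or 26).
#' @return Named numeric `c(FDRc, FNRc, DER, OER)` (NaN where undefined).
#' @export
cluster_metrics <- function(gold, auto, connectivity = 26) {
  check_same_grid(gold, auto)
  cg <- connected_components(gold, connectivity)
  ca <- connected_components(auto, connectivity)
  lg <- as.vector(cg$labels); la <- as.vector(ca$labels)
  both <- lg > 0L & la > 0L
  og <- unique(lg[both])          # gold clusters with some overlap
  oa <- unique(la[both])          # automated clusters with some overlap
  n_int <- sum(both)

  size_g <- tabulate(lg[lg > 0L], cg$n)
  size_a <- tabulate(la[la > 0L], ca$n)
  mta <- (sum(size_g) + sum(size_a)) / 2

  matched_g <- sum(size_g[og]); matched_a <- sum(size_a[oa])
  der <- ((sum(size_g) - matched_g) + (sum(size_a) - matched_a)) / mta
  oer <- (matched_g + matched_a - 2 * n_int) / mta

  c(FDRc = if (ca$n) (ca$n - length(oa)) / ca$n else NaN,
    FNRc = if (cg$n) (cg$n - length(og)) / cg$n else NaN,
    DER = der, OER = oer)
}

#' Intraclass correlation of lesion volumes, ICC(A,1)
#'
#' Two-way random effects, absolute agreement, single measure, computed
#' from the ANOVA mean squares over the n subject x 2 rater (gold,
#' automated) volume table:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, `k = 2`.
#'
#' @param gold_volumes,auto_volumes paired numeric vectors (mm^3), n >= 3.
#' @return The ICC (a value in `[-1, 1]`).
#' @export
icc_agreement <- function(gold_volumes, auto_volumes) {
  n <- length(gold_volumes)
  if (length(auto_volumes) != n) stop("volume lists must be paired", call. = FALSE)
  if (n < 3) stop("ICC needs at least 3 paired volumes", call. = FALSE)
  y <- cbind(gold_volumes, auto_volumes)
  k <- 2
  grand <- mean(y)
  if (sum((y - grand)^2) == 0)
    stop("degenerate: zero total variance in volumes", call. = FALSE)
  ssr <- k * sum((rowMeans(y) - grand)^2)
  ssc <- n * sum((colMeans(y) - grand)^2)
  sst <- sum((y - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Score a cohort of gold/automated mask pairs
#'
#' Computes the full per-subject metric suite plus cohort means (over
#' subjects with defined values) and the volume ICC. Column order follows
#' the conventional report shape: SI, FDR, FNR, FDRc, FNRc, DER, OER (+
#' volumes), with ICC as a cohort-level scalar.
#'
#' @param pairs list of `list(gold = , auto = )` [label_mask()] pairs;
#'   optionally named by subject.
#' @param connectivity cluster adjacency.
#' @return An object of class `cohort_report`: `subjects` (data.frame),
#'   `means` (named numeric), `icc` (NA when n < 3), `n_undefined`.
#' @export
cohort_report <- function(pairs, connectivity = 26) {
  if (!length(pairs)) stop("need at least one subject", call. = FALSE)
  ids <- names(pairs)
  if (is.null(ids)) ids <- sprintf("subj%03d", seq_along(pairs))
  rows <- lapply(seq_along(pairs), function(i) {
    g <- pairs[[i]]$gold; a <- pairs[[i]]$auto
    vm <- voxel_metrics(g, a)
    cm <- cluster_metrics(g, a, connectivity)
    data.frame(subject = ids[i], t(vm), t(cm),
               gold_mm3 = sum(g$data) * vox_volume_mm3(g),
               auto_mm3 = sum(a$data) * vox_volume_mm3(a),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  metric_cols <- c("SI", "FDR", "FNR", "FDRc", "FNRc", "DER", "OER")
  means <- vapply(metric_cols, function(cn) mean(df[[cn]], na.rm = TRUE),
                  numeric(1))
  n_undef <- vapply(metric_cols, function(cn) sum(is.nan(df[[cn]])),
                    integer(1))
  icc <- if (nrow(df) >= 3 && sum((cbind(df$gold_mm3, df$auto_mm3) -
                                     mean(c(df$gold_mm3, df$auto_mm3)))^2) > 0)
    icc_agreement(df$gold_mm3, df$auto_mm3) else NA_real_
  structure(list(subjects = df, means = means, icc = icc,
                 n_undefined = n_undef),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, digits = 3, ...) {
  cat(sprintf("WMH segmentation report (%d subjects)\n", nrow(x$subjects)))
  cat("cohort means:\n")
  print(round(x$means, digits))
  cat(sprintf("volume ICC(A,1): %s\n",
              if (is.na(x$icc)) "NA (needs >= 3 subjects)"
              else format(round(x$icc, digits))))
  if (any(x$n_undefined > 0))
    cat("undefined (excluded) per metric:",
        paste(sprintf("%s=%d", names(x$n_undefined)[x$n_undefined > 0],
                      x$n_undefined[x$n_undefined > 0]), collapse = ", "),
        "\n")
  invisible(x)
}

#' Write a cohort report as CSV
#'
#' Per-subject rows followed by a `MEAN` row; the ICC is placed on the
#' `MEAN` row in its own column.
#'
#' @param report a [cohort_report()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  df <- report$subjects
  df$ICC <- NA_real_
  mrow <- df[1, ]
  mrow$subject <- "MEAN"
  for (cn in names(report$means)) mrow[[cn]] <- report$means[[cn]]
  mrow$gold_mm3 <- mean(df$gold_mm3)
  mrow$auto_mm3 <- mean(df$auto_mm3)
  mrow$ICC <- report$icc
  write.csv(rbind(df, mrow), path, row.names = FALSE)
  invisible(path)
}
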