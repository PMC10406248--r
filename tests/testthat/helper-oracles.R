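# Independent brute-force oracles used to cross-check the compiled
# implementations, plus small-phantom builders shared across tests.

# flood-fill connected components (plain-R BFS)
flood_fill_components <- function(arr, connectivity = 26) {
  d <- dim(arr)
  offs <- expand.grid(a = -1:1, b = -1:1, c = -1:1)
  m <- abs(offs$a) + abs(offs$b) + abs(offs$c)
  keep <- m > 0 & switch(as.character(connectivity),
                         "6" = m <= 1, "18" = m <= 2, "26" = m <= 3)
  offs <- offs[keep, ]
  lab <- array(0L, d)
  nxt <- 0L
  for (s in which(arr == 1L)) {
    if (lab[s] > 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(v, d)
      for (r in seq_len(nrow(offs))) {
        p <- ijk + c(offs$a[r], offs$b[r], offs$c[r])
        if (any(p < 1) || any(p > d)) next
        w <- p[1] + d[1] * ((p[2] - 1) + d[2] * (p[3] - 1))
        if (arr[w] == 1L && lab[w] == 0L) { lab[w] <- nxt; queue <- c(queue, w) }
      }
    }
  }
  list(labels = lab, n = nxt)
}

# O(N*M) exact nearest-foreground-voxel distance
brute_edt <- function(arr, voxel_size) {
  d <- dim(arr)
  fg <- which(arr == 1L)
  co_fg <- (arrayInd(fg, d) - 1) %*% diag(voxel_size)
  out <- array(0, d)
  co_all <- (arrayInd(seq_len(prod(d)), d) - 1) %*% diag(voxel_size)
  for (i in seq_len(prod(d))) {
    dif <- sweep(co_fg, 2, co_all[i, ])
    out[i] <- sqrt(min(rowSums(dif^2)))
  }
  out
}

# exhaustive-search k-NN probability with (distance, index) tie-break
knn_oracle <- function(train, labels, query, k) {
  apply(query, 1, function(q) {
    d2 <- colSums((t(train) - q)^2)
    mean(labels[order(d2, seq_along(d2))[1:k]])
  })
}

# cluster metrics by explicit component pairing
cluster_metrics_oracle <- function(gold, auto, connectivity = 26) {
  cg <- flood_fill_components(gold$data, connectivity)
  ca <- flood_fill_components(auto$data, connectivity)
  gsets <- lapply(seq_len(cg$n), function(l) which(cg$labels == l))
  asets <- lapply(seq_len(ca$n), function(l) which(ca$labels == l))
  g_matched <- vapply(gsets, function(g) any(auto$data[g] == 1L), logical(1))
  a_matched <- vapply(asets, function(a) any(gold$data[a] == 1L), logical(1))
  mta <- (sum(gold$data) + sum(auto$data)) / 2
  n_int <- sum(gold$data == 1L & auto$data == 1L)
  der <- (sum(lengths(gsets)[!g_matched]) + sum(lengths(asets)[!a_matched])) / mta
  oer <- (sum(lengths(gsets)[g_matched]) + sum(lengths(asets)[a_matched]) -
            2 * n_int) / mta
  c(FDRc = if (ca$n) sum(!a_matched) / ca$n else NaN,
    FNRc = if (cg$n) sum(!g_matched) / cg$n else NaN,
    DER = der, OER = oer)
}

# ICC(A,1) through R's own two-way ANOVA decomposition
icc_oracle_aov <- function(gold, auto) {
  n <- length(gold)
  df <- data.frame(y = c(gold, auto),
                   subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# ---- shared phantom fixtures --------------------------------------------

small_geom <- function(...) {
  lesion_geometry(shape = c(32, 32, 32), brain_axes_mm = c(13, 14, 12),
                  ventricle_axes_mm = c(2.5, 6, 4), ventricle_sep_mm = 5,
                  n_wmh_clusters = c(4, 7), wmh_radius_range_mm = c(1.5, 3),
                  d_pv = 6, stroke_radius_mm = 5, ...)
}

small_cohort <- function(n, base_seed = 1, noise = 10, site = site_effect(),
                         ...) {
  tis <- tissue_model(noise_sd = c(FLAIR = noise, T1 = noise, T2 = noise))
  generate_cohort(n, tis, small_geom(...), site, base_seed = base_seed)
}

quick_settings <- function(..., n_lesion = 200, n_nonlesion = 400, k = 15) {
  segmentation_settings(
    feature_config = feature_config(c("FLAIR", "T1")),
    sampling_config = sampling_config("any", n_lesion, n_nonlesion),
    k = k, tau = 0.85, ...)
}

random_mask <- function(dims, p = 0.1, voxel_size = c(1, 1, 1)) {
  label_mask(array(as.integer(runif(prod(dims)) < p), dims), voxel_size)
}
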