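# The experimental engine: phased one-factor-at-a-time grid search over the
# segmenter's user-settings space, scored by leave-one-out cross-validation
# on (mean SI, volume ICC, mean FNRc) with the 2-of-3-metric selection
# rule; plus the same-site / cross-site / mixed-sample validation
# experiment with an unsupervised GMM arm.

#' The user-settings grid
#'
#' Option lists for the six searched dimensions. Training-point options are
#' `(lesion, nonlesion)` pairs; `("ALL","EQUAL")` means every gold voxel
#' with an equal number of non-lesion points. `extended_points = TRUE`
#' appends larger non-lesion counts (10000, 20000, 40000, 58000 with 2000
#' lesion points) to the search.
#'
#' @param modalities_options list of modality vectors.
#' @param sw_options spatial-weighting values.
#' @param patch_options patch sizes.
#' @param location_options non-lesion sampling locations.
#' @param points_options list of `(lesion, nonlesion)` pairs.
#' @param tau_options probability thresholds.
#' @param extended_points append the larger non-lesion counts?
#' @return An object of class `settings_grid`.
#' @export
settings_grid <- function(
    modalities_options = list(c("FLAIR", "T1"), c("FLAIR", "T1", "T2")),
    sw_options = c(0, 1, 5, 10),
    patch_options = c(0, 3, 6, 9),
    location_options = c("any", "noborder", "surround"),
    points_options = list(c("ALL", "EQUAL"), c("2000", "2000"),
                          c("2000", "10000")),
    tau_options = c(0.8, 0.85, 0.9, 0.95, 0.99),
    extended_points = FALSE) {
  if (extended_points) {
    for (nn in c("10000", "20000", "40000", "58000")) {
      cand <- c("2000", nn)
      if (!any(vapply(points_options, identical, logical(1), cand)))
        points_options <- c(points_options, list(cand))
    }
  }
  g <- list(modalities = modalities_options, sw = sw_options,
            patch = patch_options, location = location_options,
            points = points_options, tau = tau_options)
  if (any(vapply(g, length, integer(1)) == 0L))
    stop("every option list must be non-empty", call. = FALSE)
  structure(g, class = "settings_grid")
}

# a point in the grid
grid_config <- function(modalities = c("FLAIR", "T1"), sw = 0, patch = 0,
                        location = "any", points = c("2000", "2000"),
                        tau = 0.9) {
  list(modalities = modalities, sw = sw, patch = patch, location = location,
       points = as.character(points), tau = tau)
}

config_key <- function(cfg, with_tau = TRUE) {
  k <- paste(paste(cfg$modalities, collapse = "+"), cfg$sw, cfg$patch,
             cfg$location, paste(cfg$points, collapse = "/"), sep = "|")
  if (with_tau) paste(k, cfg$tau, sep = "|") else k
}

config_label <- function(cfg) config_key(cfg)

parse_count <- function(x) if (x %in% c("ALL", "EQUAL")) x else as.integer(x)

config_to_settings <- function(cfg, base = segmentation_settings()) {
  fc <- base$feature_config
  fc$modalities <- cfg$modalities
  fc$patch_size <- as.integer(cfg$patch)
  fc$spatial_weighting <- cfg$sw
  sc <- base$sampling_config
  sc$location <- cfg$location
  sc$n_lesion <- parse_count(cfg$points[1])
  sc$n_nonlesion <- parse_count(cfg$points[2])
  segmentation_settings(feature_config = fc, sampling_config = sc,
                        k = base$k, tau = cfg$tau,
                        stroke_mode = base$stroke_mode,
                        output_dilation_mm = base$output_dilation_mm)
}

# LOO probability maps (stroke handling already applied); shared across
# threshold values, which only re-binarize.
loo_probs <- function(cohort, settings) {
  lapply(seq_along(cohort), function(i) {
    model <- wmh_knn(cohort[-i], settings)
    segment_subject(model, cohort[[i]], settings)$prob
  })
}

score_probs <- function(cohort, probs, tau, connectivity = 26) {
  pairs <- lapply(seq_along(cohort), function(i) {
    mask <- binarize(probs[[i]], tau)
    mask$data[cohort[[i]]$masks$STROKE$data == 1L] <- 0L
    list(gold = cohort[[i]]$masks$WMH_GOLD, auto = mask)
  })
  names(pairs) <- vapply(cohort, function(s) s$subject_id, character(1))
  rep <- cohort_report(pairs, connectivity)
  list(SI = unname(rep$means["SI"]), ICC = rep$icc,
       FNRc = unname(rep$means["FNRc"]), report = rep)
}

#' Leave-one-out score of a settings configuration
#'
#' For each subject: fit on the remaining subjects, segment the held-out
#' one, and score. Returns the three selection metrics (mean SI, volume
#' ICC over the LOO pairs, mean FNRc) plus the full report.
#'
#' @param cohort list of >= 3 subjects with gold masks.
#' @param settings a [segmentation_settings()].
#' @param connectivity cluster adjacency for FNRc.
#' @return List with `SI`, `ICC`, `FNRc` and `report` (a [cohort_report()]).
#' @export
loo_score <- function(cohort, settings, connectivity = 26) {
  if (length(cohort) < 3)
    stop("LOO scoring needs at least 3 subjects (ICC)", call. = FALSE)
  for (s in cohort)
    if (is.null(s$masks$WMH_GOLD))
      stop("subject without gold mask in LOO cohort", call. = FALSE)
  probs <- loo_probs(cohort, settings)
  score_probs(cohort, probs, settings$tau, connectivity)
}

beats_23 <- function(a, b) {
  wins <- sum(c(isTRUE(a$SI > b$SI), isTRUE(a$ICC > b$ICC),
                isTRUE(a$FNRc < b$FNRc)))
  wins >= 2
}

#' Select the best configuration by the 2-of-3-metric rule
#'
#' Pairwise dominance on (SI up, ICC up, FNRc down): the winner beats every
#' other configuration on at least 2 of the 3 metrics. When no
#' configuration dominates (a preference cycle, or ties), the highest mean
#' SI wins, flagged `"si_fallback"`; fully identical score sets return the
#' first configuration, flagged `"first_identical"`.
#'
#' @param scores list of score lists with elements `SI`, `ICC`, `FNRc`.
#' @return List with `index` (winner position) and `by` (selection route).
#' @export
select_best <- function(scores) {
  n <- length(scores)
  if (n < 1) stop("no configurations to select from", call. = FALSE)
  if (n == 1) return(list(index = 1L, by = "single"))
  tri <- function(s) c(s$SI, s$ICC, s$FNRc)
  ident <- all(vapply(scores, function(s)
    isTRUE(all.equal(tri(s), tri(scores[[1]]))), logical(1)))
  if (ident) {
    warning("all configurations score identically; taking the first",
            call. = FALSE)
    return(list(index = 1L, by = "first_identical"))
  }
  for (i in seq_len(n)) {
    if (all(vapply(seq_len(n)[-i], function(j)
      beats_23(scores[[i]], scores[[j]]), logical(1))))
      return(list(index = i, by = "dominance"))
  }
  si <- vapply(scores, function(s) s$SI, numeric(1))
  list(index = which.max(si), by = "si_fallback")
}

#' Phased one-factor-at-a-time optimization of the segmenter settings
#'
#' Starting from the default configuration, each phase varies one dimension
#' at a time (modalities, spatial weighting, patch size, training-point
#' location, training-point counts, then threshold) around the phase-start
#' configuration, picks the per-dimension winners by the 2-of-3 rule,
#' and adopts a candidate (the combined winners, or a single-dimension
#' winner) only if it wins the 2-of-3 comparison against the incumbent
#' without lowering mean SI — the improvement-or-equal guarantee.
#' Phases repeat until nothing changes or `max_phases` is hit. Threshold
#' sweeps reuse the leave-one-out probability maps (only re-binarizing),
#' and every evaluated configuration is cached, so re-scoring across
#' phases is free.
#'
#' @param cohort list of >= 3 training subjects.
#' @param grid a [settings_grid()].
#' @param base a [segmentation_settings()] carrying the non-searched
#'   settings (k, stroke mode, normalization).
#' @param start starting configuration (defaults: FLAIR+T1, sw 0, patch 0,
#'   location any, 2000/2000 points, tau 0.9); must be a grid member.
#' @param max_phases phase budget.
#' @param connectivity cluster adjacency.
#' @param verbose print per-phase progress.
#' @return An object of class `phased_optimization`: final `settings` and
#'   `config`, the full `trail` (data.frame of every evaluation), scores of
#'   the start/final configs, `converged`, `phases`.
#' @export
phased_optimize <- function(cohort, grid = settings_grid(),
                            base = segmentation_settings(), start = NULL,
                            max_phases = 5, connectivity = 26,
                            verbose = FALSE) {
  if (is.null(start))
    start <- grid_config(modalities = grid$modalities[[1]],
                         sw = grid$sw[1], patch = grid$patch[1],
                         location = grid$location[1],
                         points = grid$points[[1]],
                         tau = if (0.9 %in% grid$tau) 0.9 else grid$tau[1])
  for (d in names(grid)) {
    opts <- if (is.list(grid[[d]])) grid[[d]] else as.list(grid[[d]])
    if (!any(vapply(opts, identical, logical(1), start[[d]])))
      stop("start configuration is not a grid member in dimension ", d,
           call. = FALSE)
  }

  score_cache <- new.env(parent = emptyenv())
  eval_taus <- function(cfg, taus) {
    # score cfg at several taus, computing LOO probabilities at most once
    out <- vector("list", length(taus))
    missing_taus <- c()
    for (ti in seq_along(taus)) {
      cfg$tau <- taus[ti]
      key <- config_key(cfg)
      if (!is.null(score_cache[[key]])) out[[ti]] <- score_cache[[key]]
      else missing_taus <- c(missing_taus, ti)
    }
    if (length(missing_taus)) {
      cfg$tau <- taus[missing_taus[1]]
      probs <- loo_probs(cohort, config_to_settings(cfg, base))
      for (ti in missing_taus) {
        cfg$tau <- taus[ti]
        sc <- score_probs(cohort, probs, taus[ti], connectivity)
        score_cache[[config_key(cfg)]] <- sc
        out[[ti]] <- sc
      }
    }
    out
  }
  eval_one <- function(cfg) eval_taus(cfg, cfg$tau)[[1]]

  dims <- names(grid)
  current <- start
  trail <- list()
  converged <- FALSE
  phase <- 0L
  while (phase < max_phases && !converged) {
    phase <- phase + 1L
    phase_start <- current
    winners <- phase_start
    for (d in dims) {
      opts <- if (is.list(grid[[d]])) grid[[d]] else as.list(grid[[d]])
      cfgs <- lapply(opts, function(o) { c2 <- phase_start; c2[[d]] <- o; c2 })
      scores <- if (d == "tau") {
        eval_taus(phase_start, unlist(grid$tau))
      } else {
        lapply(cfgs, eval_one)
      }
      sel <- select_best(scores)
      winners[[d]] <- opts[[sel$index]]
      for (oi in seq_along(opts)) {
        trail[[length(trail) + 1L]] <- data.frame(
          phase = phase, dimension = d,
          config = config_label(cfgs[[oi]]),
          SI = scores[[oi]]$SI, ICC = scores[[oi]]$ICC,
          FNRc = scores[[oi]]$FNRc,
          winner = oi == sel$index, selection = sel$by,
          stringsAsFactors = FALSE)
      }
      if (verbose)
        message(sprintf("phase %d %-10s -> %s", phase, d,
                        config_label(cfgs[[sel$index]])))
    }
    # adoption: combined winners first, then single-dimension winners;
    # adopt only on a 2/3 win that does not lower mean SI
    candidates <- list(winners)
    for (d in dims) {
      c2 <- phase_start; c2[[d]] <- winners[[d]]
      candidates[[length(candidates) + 1L]] <- c2
    }
    keys <- vapply(candidates, config_key, character(1))
    candidates <- candidates[!duplicated(keys)]
    best <- phase_start
    best_score <- eval_one(best)
    for (cand in candidates) {
      if (config_key(cand) == config_key(best)) next
      sc <- eval_one(cand)
      if (beats_23(sc, best_score) && isTRUE(sc$SI >= best_score$SI)) {
        best <- cand; best_score <- sc
      }
    }
    converged <- config_key(best) == config_key(phase_start)
    current <- best
  }
  structure(list(
    config = current,
    settings = config_to_settings(current, base),
    start = start,
    start_score = eval_one(start),
    final_score = eval_one(current),
    trail = do.call(rbind, trail),
    converged = converged, phases = phase),
    class = "phased_optimization")
}

#' @export
print.phased_optimization <- function(x, ...) {
  cat(sprintf("<phased_optimization: %d phase(s), %s>\n", x$phases,
              if (x$converged) "converged" else "NOT converged"))
  cat("  start:", config_label(x$start),
      sprintf(" (SI %.3f, ICC %.3f, FNRc %.3f)\n", x$start_score$SI,
              x$start_score$ICC, x$start_score$FNRc))
  cat("  final:", config_label(x$config),
      sprintf(" (SI %.3f, ICC %.3f, FNRc %.3f)\n", x$final_score$SI,
              x$final_score$ICC, x$final_score$FNRc))
  invisible(x)
}

#' Same-site / cross-site / mixed-sample validation experiment
#'
#' Both cohorts are split 80/20 (seeded simple random split) into training
#' and test samples. Four supervised arms share identical settings:
#' train-A/test-A, train-B/test-B, train-A/test-B (the cross-site arm) and
#' mixed (train on both training samples, test on both test samples). An
#' unsupervised GMM arm segments each test sample without training data.
#'
#' @param cohort_a,cohort_b lists of >= 4 subjects (per-site cohorts).
#' @param settings supervised [segmentation_settings()] shared by all arms.
#' @param seed RNG seed for the splits (and the GMM fits).
#' @param train_frac training fraction of each cohort.
#' @param gmm_modalities,gmm_K,gmm_tau unsupervised-arm parameters.
#' @param connectivity cluster adjacency.
#' @return An object of class `cross_site_experiment`: `summary`
#'   (data.frame, one row per arm) and `reports` (named [cohort_report()]s).
#' @export
cross_site_experiment <- function(cohort_a, cohort_b, settings,
                                  seed = 1, train_frac = 0.8,
                                  gmm_modalities = c("FLAIR", "T1"),
                                  gmm_K = 4, gmm_tau = 0.1,
                                  connectivity = 26) {
  na <- length(cohort_a); nb <- length(cohort_b)
  if (na < 4 || nb < 4)
    stop("cohorts too small to split (need >= 4 subjects each)", call. = FALSE)
  n_tr_a <- max(1, round(train_frac * na)); n_tr_b <- max(1, round(train_frac * nb))
  if (n_tr_a >= na || n_tr_b >= nb)
    stop("cohorts too small to split at this training fraction", call. = FALSE)
  # per-cohort splits from the same seed: identical cohorts (the identity
  # null case) then share identical splits
  ia <- with_seed(seed, sort(sample(na, n_tr_a)))
  ib <- with_seed(seed, sort(sample(nb, n_tr_b)))
  a_train <- cohort_a[ia]; a_test <- cohort_a[-ia]
  b_train <- cohort_b[ib]; b_test <- cohort_b[-ib]

  score_arm <- function(model, test) {
    pairs <- lapply(test, function(s)
      list(gold = s$masks$WMH_GOLD,
           auto = segment_subject(model, s)$mask))
    names(pairs) <- vapply(test, function(s) s$subject_id, character(1))
    cohort_report(pairs, connectivity)
  }
  model_a <- wmh_knn(a_train, settings)
  model_b <- wmh_knn(b_train, settings)
  model_mix <- wmh_knn(c(a_train, b_train), settings)

  reports <- list(
    same_site_a = score_arm(model_a, a_test),
    same_site_b = score_arm(model_b, b_test),
    cross_site = score_arm(model_a, b_test),
    mixed = score_arm(model_mix, c(a_test, b_test)))

  gmm_arm <- function(test, offset) {
    pairs <- lapply(seq_along(test), function(j) {
      seg <- segment_unsupervised(test[[j]], modalities = gmm_modalities,
                                  K = gmm_K, tau = gmm_tau,
                                  seed = seed + offset + j)
      list(gold = test[[j]]$masks$WMH_GOLD, auto = seg$mask)
    })
    names(pairs) <- vapply(test, function(s) s$subject_id, character(1))
    cohort_report(pairs, connectivity)
  }
  reports$gmm_site_a <- gmm_arm(a_test, 1000L)
  reports$gmm_site_b <- gmm_arm(b_test, 2000L)

  summary <- do.call(rbind, lapply(names(reports), function(arm) {
    r <- reports[[arm]]
    data.frame(arm = arm, n_test = nrow(r$subjects),
               SI = unname(r$means["SI"]), FDR = unname(r$means["FDR"]),
               FNR = unname(r$means["FNR"]), FDRc = unname(r$means["FDRc"]),
               FNRc = unname(r$means["FNRc"]), DER = unname(r$means["DER"]),
               OER = unname(r$means["OER"]), ICC = r$icc,
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summary, reports = reports,
                 split = list(a_train = ia, b_train = ib), seed = seed),
            class = "cross_site_experiment")
}

#' @export
print.cross_site_experiment <- function(x, digits = 3, ...) {
  cat("Cross-site validation experiment\n")
  df <- x$summary
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
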