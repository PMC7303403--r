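# End-to-end orchestration: simulate (or accept) a cohort, band-filter,
# epoch, extract GFP peaks, cluster global maps, back-fit, smooth, compute
# per-subject statistics and transitions, run the group battery, the
# syntax permutation test, and LOO-CV classification.

#' Pipeline configuration
#'
#' @param cohort_cfg A [cohort_sim_config()] describing the input cohort.
#' @param bands Band names to analyze (first entry is the primary band used
#'   for group statistics and the syntax test); subset of
#'   `names(band_specs())`.
#' @param k Number of microstates (default 4; 3, 5 and 6 supported).
#' @param peaks_per_subject GFP peaks contributed per subject (default 1000).
#' @param min_peak_distance_ms Minimum GFP-peak spacing (default 10 ms).
#' @param sd_threshold GFP-peak exclusion multiplier (default 2).
#' @param smoothing_ms Minimum segment duration (default 30 ms).
#' @param n_restarts K-means restarts (default 50).
#' @param kmeans_max_iter K-means iteration cap (default 1000).
#' @param n_permutations Syntax permutation count (default 5000).
#' @param classifiers Character vector of classifier names for LOO-CV
#'   (default `"multinomial"`); empty to skip classification.
#' @param classify_bands `"broadband"` or `"all"` feature set for
#'   classification.
#' @param master_seed Master seed for all stochastic stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort_cfg = cohort_sim_config(),
                            bands = "broadband",
                            k = 4,
                            peaks_per_subject = 1000,
                            min_peak_distance_ms = 10,
                            sd_threshold = 2,
                            smoothing_ms = 30,
                            n_restarts = 50,
                            kmeans_max_iter = 1000,
                            n_permutations = 5000,
                            classifiers = "multinomial",
                            classify_bands = "broadband",
                            master_seed = 1L) {
  if (k < 2) stop("k must be at least 2")
  stopifnot(peaks_per_subject > 0, min_peak_distance_ms > 0,
            smoothing_ms >= 0, n_restarts > 0, n_permutations > 0)
  if (!all(bands %in% names(band_specs())))
    stop("unknown band(s): ",
         paste(setdiff(bands, names(band_specs())), collapse = ", "))
  structure(as.list(environment()), class = "pipeline_config")
}

# Per-subject feature vector for one band: duration/occurrence/coverage per
# map plus the 12 transition percentages.  Features are keyed by cluster
# index (m1..mK); canonical letters live in the label metadata, since
# band-specific maps can carry hybrid labels.
subject_feature_row <- function(stats, profile, k) {
  pm <- stats$per_map
  v <- c(pm$duration_ms, pm$occurrence_per_s, pm$coverage_pct,
         profile$observed)
  names(v) <- c(paste0("duration_m", seq_len(k)),
                paste0("occurrence_m", seq_len(k)),
                paste0("coverage_m", seq_len(k)),
                paste0("trans_", gsub("_to_", "_", names(profile$observed)),
                       "_pct"))
  v
}

# Feature column names of the 24-comparison battery for one band.
battery_feature_names <- function(k, pair_names) {
  c(paste0("duration_m", seq_len(k)),
    paste0("occurrence_m", seq_len(k)),
    paste0("coverage_m", seq_len(k)),
    paste0("trans_", gsub("_to_", "_", pair_names), "_pct"))
}

# Analyze one band of an already-simulated cohort: filter, epoch, peaks,
# cluster, label, back-fit, smooth, per-subject stats + transitions.
.analyze_band <- function(recordings, templates, band, cfg, seed) {
  epochs <- lapply(recordings, function(rec) {
    epoch_recording(filter_band(rec, band), 1)
  })
  peaks <- lapply(seq_along(epochs), function(i) {
    extract_gfp_peaks(epochs[[i]],
                      min_distance_ms = cfg$min_peak_distance_ms,
                      max_peaks = cfg$peaks_per_subject,
                      sd_threshold = cfg$sd_threshold,
                      subject_id = as.character(i))
  })
  maps <- aggregate_and_cluster(peaks, k = cfg$k,
                                peaks_per_subject = cfg$peaks_per_subject,
                                restarts = cfg$n_restarts,
                                max_iter = cfg$kmeans_max_iter,
                                seed = seed)
  if (cfg$k == nrow(templates$maps))
    maps <- assign_canonical_labels(maps, templates)
  segs <- lapply(epochs, function(ep) {
    smooth_segmentation(backfit(ep, maps), cfg$smoothing_ms)
  })
  stats <- lapply(segs, compute_stats)
  profiles <- lapply(segs, transition_profile)
  feat <- t(vapply(seq_along(segs), function(i)
    subject_feature_row(stats[[i]], profiles[[i]], cfg$k),
    numeric(3 * cfg$k + cfg$k * (cfg$k - 1))))
  list(maps = maps, segmentations = segs, stats = stats,
       profiles = profiles, features = feat,
       gev = vapply(stats, `[[`, numeric(1), "gev_total"))
}

#' Run the full microstate analysis pipeline
#'
#' Simulates (or takes) a cohort, then for every requested band: filters,
#' epochs, extracts GFP-peak topographies, clusters cohort-level global
#' maps with polarity-invariant modified K-means, back-fits and smooths the
#' segmentation, and computes per-subject statistics and transition
#' profiles.  On the primary band it runs the ANCOVA + FDR group battery
#' and the syntax permutation test; finally it runs LOO-CV classification
#' on the assembled feature matrix.  Fully deterministic given
#' `master_seed`.
#'
#' @param cfg A [pipeline_config()].
#' @param cohort Optional pre-simulated `sim_cohort` (skips simulation).
#' @param out_dir Optional directory; when given, feature tables, group
#'   statistics, maps and a JSON manifest are written there.
#' @return A `pipeline_result` list: `cohort`, per-band `bands` (maps,
#'   stats, features, GEV), `group_stats`, `syntax`, `classification`,
#'   `features` (data frame with covariates), `seeds`.
#' @export
run_pipeline <- function(cfg, cohort = NULL, out_dir = NULL) {
  if (!inherits(cfg, "pipeline_config")) stop("cfg must be a pipeline_config")
  seeds <- .child_seeds(cfg$master_seed, length(cfg$bands) + 2L)
  if (is.null(cohort)) {
    sim_cfg <- cfg$cohort_cfg
    sim_cfg$seed <- seeds[length(cfg$bands) + 1L]
    cohort <- simulate_cohort(sim_cfg)
  }
  templates <- cohort$templates
  band_results <- list()
  for (bi in seq_along(cfg$bands)) {
    band_results[[cfg$bands[bi]]] <-
      .analyze_band(cohort$recordings, templates, cfg$bands[bi], cfg,
                    seed = seeds[bi])
  }
  primary <- band_results[[1L]]
  k <- cfg$k
  feat_df <- cbind(cohort$covariates,
                   as.data.frame(primary$features),
                   gev = primary$gev)
  battery <- battery_feature_names(
    k, names(primary$profiles[[1L]]$observed))
  covariate_cols <- c("age", "sex", "education_years", "med_antipsychotic",
                      "med_antidepressant", "med_hypnotic",
                      "med_antidementia", "med_painkiller")
  group_stats <- run_group_battery(feat_df, battery,
                                   group_col = "group",
                                   covariate_cols = covariate_cols,
                                   m = length(battery))
  obs <- t(vapply(primary$profiles, `[[`, numeric(k * (k - 1)), "observed"))
  exp <- t(vapply(primary$profiles, `[[`, numeric(k * (k - 1)), "expected"))
  syntax <- syntax_permutation_test(obs, exp, n_perm = cfg$n_permutations,
                                    seed = seeds[length(cfg$bands) + 2L])
  classification <- NULL
  if (length(cfg$classifiers)) {
    band_feats <- lapply(band_results, `[[`, "features")
    want <- if (identical(cfg$classify_bands, "all"))
      c("broadband", "delta", "theta", "alpha", "beta") else "broadband"
    if (all(want %in% names(band_feats))) {
      xraw <- do.call(cbind, lapply(want, function(b) {
        m <- band_feats[[b]]
        colnames(m) <- paste(b, colnames(m), sep = ".")
        m
      }))
      classification <- lapply(cfg$classifiers, function(mod)
        loo_cv(xraw, cohort$covariates$group, model = mod))
      names(classification) <- cfg$classifiers
    }
  }
  result <- structure(list(cohort = cohort, bands = band_results,
                           features = feat_df, group_stats = group_stats,
                           syntax = syntax,
                           classification = classification,
                           config = cfg, seeds = seeds),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' Write pipeline artifacts to a run directory
#'
#' Writes the per-subject feature table, the group-statistics table, the
#' global maps (channels x K CSV) per band, the syntax result and a JSON
#' manifest (seeds, configuration summary, map labels, realized sizes).
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$features,
                   file.path(out_dir, "subject_features.csv"),
                   row.names = FALSE)
  utils::write.csv(result$group_stats,
                   file.path(out_dir, "group_stats.csv"), row.names = FALSE)
  for (b in names(result$bands)) {
    m <- result$bands[[b]]$maps
    utils::write.csv(as.data.frame(t(m$maps)),
                     file.path(out_dir, sprintf("maps_%s.csv", b)))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("microstatr")),
    master_seed = result$config$master_seed,
    child_seeds = result$seeds,
    k = result$config$k,
    bands = result$config$bands,
    n_subjects = nrow(result$features),
    map_labels = lapply(result$bands, function(b) b$maps$labels),
    syntax_p = result$syntax$p_value,
    classification_accuracy = lapply(result$classification, `[[`,
                                     "accuracy"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Microstate pipeline result:", nrow(x$features), "subjects,",
      "bands:", paste(names(x$bands), collapse = ", "), "\n")
  cat(sprintf("  primary-band mean GEV: %.3f\n",
              mean(x$bands[[1L]]$gev)))
  cat(sprintf("  syntax permutation p = %.4f\n", x$syntax$p_value))
  if (!is.null(x$classification)) {
    for (nm in names(x$classification))
      cat(sprintf("  %s LOO accuracy: %.1f%%\n", nm,
                  x$classification[[nm]]$accuracy))
  }
  invisible(x)
}
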