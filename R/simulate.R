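# Synthetic EEG with planted microstate structure.
#
# The signal model is a semi-Markov chain over K template topographies:
# dwell times are gamma-distributed per map (so duration and occurrence can
# be planted independently of the transition structure), the next state is
# drawn from a row-normalized transition-weight matrix, and the active map
# is emitted under a rectified-sinusoid amplitude envelope whose maxima
# create the discrete GFP peaks that peak-picking expects.  Sensor noise is
# spatially white; the emitted frames are average-referenced.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive reproducible child seeds from a master seed.
.child_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Subject simulation configuration
#'
#' @param templates A `template_maps` object (the planted maps).
#' @param dwell_mean_ms Per-map mean dwell time in milliseconds (length K).
#' @param dwell_shape Gamma shape parameter of the dwell-time distribution
#'   (dimensionless; larger = more regular dwells).
#' @param transition_weights K x K nonnegative matrix of transition weights
#'   with zero diagonal; rows are normalized to probabilities when the next
#'   state is drawn.  Default: uniform over the other maps.
#' @param carrier_freq_hz Frequency of the rectified-sinusoid GFP envelope
#'   (Hz); peaks occur at twice this rate.
#' @param snr Ratio of state-signal RMS to sensor-noise RMS (`Inf` = clean).
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz.
#' @return A `subject_sim_config` list, validated.
#' @export
subject_sim_config <- function(templates = make_canonical_maps(),
                               dwell_mean_ms = c(75, 80, 85, 100),
                               dwell_shape = 2,
                               transition_weights = NULL,
                               carrier_freq_hz = 10,
                               snr = 8,
                               duration_s = 60,
                               fs = 200) {
  k <- nrow(templates$maps)
  if (length(dwell_mean_ms) == 1L) dwell_mean_ms <- rep(dwell_mean_ms, k)
  if (is.null(transition_weights)) {
    transition_weights <- matrix(1, k, k); diag(transition_weights) <- 0
  }
  cfg <- list(templates = templates, dwell_mean_ms = dwell_mean_ms,
              dwell_shape = dwell_shape,
              transition_weights = transition_weights,
              carrier_freq_hz = carrier_freq_hz, snr = snr,
              duration_s = duration_s, fs = fs)
  validate_subject_sim_config(cfg)
  structure(cfg, class = "subject_sim_config")
}

validate_subject_sim_config <- function(cfg) {
  k <- nrow(cfg$templates$maps)
  if (length(cfg$dwell_mean_ms) != k || any(cfg$dwell_mean_ms <= 0))
    stop("dwell_mean_ms must be positive, one value per map")
  if (cfg$dwell_shape <= 0) stop("dwell_shape must be positive")
  tw <- cfg$transition_weights
  if (!is.matrix(tw) || any(dim(tw) != k))
    stop("transition_weights must be a K x K matrix")
  if (any(tw < 0)) stop("transition_weights must be nonnegative")
  if (any(diag(tw) != 0)) stop("transition_weights diagonal must be 0")
  if (any(rowSums(tw) <= 0)) stop("every map needs a positive exit weight")
  if (!(cfg$snr > 0)) stop("snr must be positive")
  if (!is.finite(cfg$duration_s) || cfg$duration_s <= 0)
    stop("duration_s must be positive")
  if (!is.finite(cfg$fs) || cfg$fs <= 0) stop("fs must be positive")
  if (cfg$fs <= 2 * cfg$carrier_freq_hz)
    stop("fs must exceed twice the carrier frequency")
  invisible(cfg)
}

# Draw a semi-Markov state path of exactly n_samples samples.
.draw_state_path <- function(cfg, n_samples) {
  k <- nrow(cfg$templates$maps)
  scale_ms <- cfg$dwell_mean_ms / cfg$dwell_shape
  probs <- cfg$transition_weights / rowSums(cfg$transition_weights)
  states <- integer(0)
  s <- sample.int(k, 1L)
  total <- 0L
  while (total < n_samples) {
    dwell_ms <- stats::rgamma(1L, shape = cfg$dwell_shape,
                              scale = scale_ms[s])
    len <- max(1L, as.integer(round(dwell_ms * cfg$fs / 1000)))
    states <- c(states, rep(s, len))
    total <- total + len
    s <- sample.int(k, 1L, prob = probs[s, ])
  }
  states[seq_len(n_samples)]
}

#' Simulate one subject's EEG with planted microstate sequence
#'
#' Draws a hidden semi-Markov state path, emits the active template map
#' under a rectified-sinusoid envelope, adds white sensor noise scaled to
#' the configured SNR, and average-references the result.
#'
#' @param cfg A [subject_sim_config()].
#' @param seed Integer seed; identical seeds give identical recordings.
#' @return A list with `recording` (an `eeg_recording`), `states` (the
#'   ground-truth per-sample map index), and `map_labels`.
#' @export
simulate_subject <- function(cfg, seed = NULL) {
  validate_subject_sim_config(cfg)
  .with_seed(seed, {
    n <- as.integer(round(cfg$duration_s * cfg$fs))
    states <- .draw_state_path(cfg, n)
    tt <- seq_len(n) - 1L
    env <- abs(sin(2 * pi * cfg$carrier_freq_hz * tt / cfg$fs))
    # channels x samples: active map scaled by the envelope
    clean <- t(cfg$templates$maps[states, , drop = FALSE] * env)
    if (is.finite(cfg$snr)) {
      sig_rms <- sqrt(mean(clean^2))
      noise <- matrix(stats::rnorm(length(clean), sd = sig_rms / cfg$snr),
                      nrow = nrow(clean))
      data <- clean + noise
    } else {
      data <- clean
    }
    rec <- recording(data, fs = cfg$fs, montage = cfg$templates$montage)
    rec <- average_reference(rec)
    list(recording = rec, states = states,
         map_labels = cfg$templates$labels)
  })
}

#' Cohort simulation configuration
#'
#' Defines a multi-group cohort with per-group offsets on the mean dwell
#' time of each map (the planted group effect) and a covariate model whose
#' defaults emulate the marginals of a memory-clinic cohort of healthy
#' controls (HC), mild cognitive impairment (MCI) and Alzheimer's disease
#' (AD): ages around 66/70/75 years, education 14/12/10 years, roughly
#' balanced sex, sparse medication use, and MMSE/word-list scores declining
#' across groups.
#'
#' @param groups List of group definitions, each a list with `name`,
#'   `n` (subjects, >= 2) and `dwell_offset_ms` (length-K additive offset on
#'   the per-map mean dwell).  Default: HC (no offset), MCI and AD with
#'   +15 ms on map A, mimicking the increased map-A duration/occurrence/
#'   coverage planted effect.
#' @param base_cfg A [subject_sim_config()] giving the shared signal model.
#' @param covariate_model Optional per-group list of covariate parameters
#'   (see [default_covariate_model()]).
#' @param seed Master integer seed.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(groups = NULL,
                              base_cfg = subject_sim_config(),
                              covariate_model = NULL,
                              seed = 1L) {
  k <- nrow(base_cfg$templates$maps)
  if (is.null(groups)) {
    off <- c(15, rep(0, k - 1L))
    groups <- list(
      list(name = "HC",  n = 135L, dwell_offset_ms = rep(0, k)),
      list(name = "MCI", n = 117L, dwell_offset_ms = off),
      list(name = "AD",  n = 117L, dwell_offset_ms = off))
  }
  if (length(groups) == 0L) stop("at least one group is required")
  for (g in groups) {
    if (is.null(g$name) || is.null(g$n)) stop("each group needs name and n")
    if (g$n < 2L) stop("each group needs at least 2 subjects")
    if (length(g$dwell_offset_ms) != k)
      stop("dwell_offset_ms must have one value per map")
  }
  if (is.null(covariate_model)) {
    covariate_model <- default_covariate_model(vapply(groups, `[[`,
                                                      character(1), "name"))
  }
  .validate_covariate_model(covariate_model)
  structure(list(groups = groups, base_cfg = base_cfg,
                 covariate_model = covariate_model, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Default cohort covariate model
#'
#' Per-group means/SDs for age and education, sex proportion, medication
#' flag probabilities, and cognitive-score distributions.  Values follow
#' typical memory-clinic marginals (HC / MCI / AD); unknown groups fall
#' back to the HC parameters.
#'
#' @param group_names Character vector of group names.
#' @return Named list of per-group parameter lists.
#' @export
default_covariate_model <- function(group_names = c("HC", "MCI", "AD")) {
  ref <- list(
    HC  = list(age_mean = 66.44, age_sd = 7.64, edu_mean = 13.89,
               edu_sd = 3.61, sex_p_female = 0.607,
               med_p = c(antipsychotic = 0.00, antidepressant = 0.00,
                         hypnotic = 0.022, antidementia = 0.00,
                         painkiller = 0.03),
               mmse_mean = 28.91, mmse_sd = 1.34,
               cerad_learning_mean = 20.49, cerad_learning_sd = 3.99,
               cerad_recall_mean = 7.39, cerad_recall_sd = 1.69),
    MCI = list(age_mean = 70.15, age_sd = 8.13, edu_mean = 11.57,
               edu_sd = 3.92, sex_p_female = 0.53,
               med_p = c(antipsychotic = 0.009, antidepressant = 0.214,
                         hypnotic = 0.103, antidementia = 0.017,
                         painkiller = 0.051),
               mmse_mean = 27.11, mmse_sd = 2.16,
               cerad_learning_mean = 15.25, cerad_learning_sd = 4.29,
               cerad_recall_mean = 3.66, cerad_recall_sd = 2.34),
    AD  = list(age_mean = 75.49, age_sd = 7.65, edu_mean = 10.07,
               edu_sd = 3.39, sex_p_female = 0.607,
               med_p = c(antipsychotic = 0.034, antidepressant = 0.154,
                         hypnotic = 0.051, antidementia = 0.154,
                         painkiller = 0.034),
               mmse_mean = 23.52, mmse_sd = 3.79,
               cerad_learning_mean = 11.06, cerad_learning_sd = 3.83,
               cerad_recall_mean = 1.52, cerad_recall_sd = 1.64))
  out <- lapply(group_names, function(g) {
    if (g %in% names(ref)) ref[[g]] else ref$HC
  })
  names(out) <- group_names
  out
}

.validate_covariate_model <- function(cm) {
  for (g in cm) {
    if (g$age_sd < 0 || g$edu_sd < 0 || g$mmse_sd < 0)
      stop("covariate SDs must be nonnegative")
    probs <- c(g$sex_p_female, g$med_p)
    if (any(probs < 0 | probs > 1))
      stop("covariate probabilities must lie in [0, 1]")
  }
  invisible(cm)
}

.draw_covariates <- function(par, n, group, ids) {
  data.frame(
    subject_id = ids,
    group = group,
    age = stats::rnorm(n, par$age_mean, par$age_sd),
    sex = stats::rbinom(n, 1L, par$sex_p_female),
    education_years = pmax(5, stats::rnorm(n, par$edu_mean, par$edu_sd)),
    med_antipsychotic = stats::rbinom(n, 1L, par$med_p[["antipsychotic"]]),
    med_antidepressant = stats::rbinom(n, 1L, par$med_p[["antidepressant"]]),
    med_hypnotic = stats::rbinom(n, 1L, par$med_p[["hypnotic"]]),
    med_antidementia = stats::rbinom(n, 1L, par$med_p[["antidementia"]]),
    med_painkiller = stats::rbinom(n, 1L, par$med_p[["painkiller"]]),
    mmse = pmin(30, stats::rnorm(n, par$mmse_mean, par$mmse_sd)),
    cerad_learning = pmax(0, stats::rnorm(n, par$cerad_learning_mean,
                                          par$cerad_learning_sd)),
    cerad_recall = pmax(0, stats::rnorm(n, par$cerad_recall_mean,
                                        par$cerad_recall_sd)),
    stringsAsFactors = FALSE)
}

#' Simulate a multi-group cohort
#'
#' Simulates every subject with group-specific dwell-time offsets and draws
#' covariates from the cohort covariate model.  Fully deterministic given
#' the config seed: per-subject child seeds are derived from it.
#'
#' @param cfg A [cohort_sim_config()].
#' @return A `sim_cohort` list with `recordings` (list of `eeg_recording`),
#'   `states` (list of ground-truth label vectors), `covariates`
#'   (data.frame, one row per subject), `ground_truth` (per-subject planted
#'   dwell means), and `templates`.
#' @export
simulate_cohort <- function(cfg) {
  if (!inherits(cfg, "cohort_sim_config")) stop("cfg must be a cohort_sim_config")
  n_total <- sum(vapply(cfg$groups, `[[`, numeric(1), "n"))
  seeds <- .child_seeds(cfg$seed, n_total + length(cfg$groups))
  cov_seeds <- utils::tail(seeds, length(cfg$groups))
  recordings <- vector("list", n_total)
  states <- vector("list", n_total)
  cov_rows <- list()
  gt <- list()
  i <- 0L
  for (gi in seq_along(cfg$groups)) {
    grp <- cfg$groups[[gi]]
    ids <- sprintf("%s_%03d", grp$name, seq_len(grp$n))
    cov_rows[[gi]] <- .with_seed(
      cov_seeds[gi],
      .draw_covariates(cfg$covariate_model[[grp$name]], grp$n, grp$name, ids))
    for (si in seq_len(grp$n)) {
      i <- i + 1L
      scfg <- cfg$base_cfg
      scfg$dwell_mean_ms <- scfg$dwell_mean_ms + grp$dwell_offset_ms
      sim <- simulate_subject(scfg, seed = seeds[i])
      recordings[[i]] <- sim$recording
      states[[i]] <- sim$states
      gt[[i]] <- data.frame(subject_id = ids[si], group = grp$name,
                            map = cfg$base_cfg$templates$labels,
                            dwell_mean_ms = scfg$dwell_mean_ms,
                            stringsAsFactors = FALSE)
    }
  }
  covariates <- do.call(rbind, cov_rows)
  rownames(covariates) <- NULL
  structure(list(recordings = recordings, states = states,
                 covariates = covariates,
                 ground_truth = do.call(rbind, gt),
                 templates = cfg$base_cfg$templates),
            class = "sim_cohort")
}

#' Write a simulated cohort to disk
#'
#' Writes one `<subject_id>.csv` per subject (samples x channels, with a
#' header of channel labels), a `covariates.csv` table, and a
#' `ground_truth.json` with the planted per-subject dwell parameters and
#' the sampling rate.
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  for (i in seq_along(cohort$recordings)) {
    rec <- cohort$recordings[[i]]
    utils::write.csv(as.data.frame(t(rec$data)),
                     file.path(dir, paste0(cohort$covariates$subject_id[i],
                                           ".csv")),
                     row.names = FALSE)
  }
  gt <- list(fs = cohort$recordings[[1]]$fs,
             montage = cohort$recordings[[1]]$montage,
             dwell_mean_ms = split(cohort$ground_truth,
                                   cohort$ground_truth$subject_id))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort:", length(x$recordings), "subjects,",
      paste(unique(x$covariates$group), collapse = "/"), "\n")
  invisible(x)
}
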