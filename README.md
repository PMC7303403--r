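# microstatr

Microstate analysis of multichannel resting-state EEG, for researchers
studying large-scale brain dynamics in aging and dementia cohorts (and
anyone who needs a tested, reproducible microstate pipeline).

EEG microstates are brief (~60–120 ms) periods during which the scalp
potential topography stays quasi-stable; resting EEG is modeled as a
sequence of a few recurring topographies, canonically labeled A–D.
`microstatr` implements the full analysis chain on 19-channel 10–20
recordings:

- **Segmentation** — global field power (GFP) peak extraction
  (10 ms minimum spacing, outlier exclusion, first 1000 peaks per
  subject), polarity-invariant *modified K-means* over the pooled peak
  topographies (assignment maximizes the squared projection
  `(xᵀm)²`; maps are dominant eigenvectors of the cluster scatter;
  50 restarts, 1000 iterations), back-fitting of the global maps to every
  sample, and rejection of segments shorter than 30 ms.
- **Statistics** — per-map duration (ms), occurrence (1/s), coverage (%)
  and GEV = Σₜ GFPₜ²ρₜ² / Σₜ GFPₜ², per frequency band (broadband ≤40 Hz,
  delta <4, theta 4–8, alpha 8–13, beta 13–30 Hz).
- **Syntax** — observed transition percentages over the 12 ordered map
  pairs vs the occurrence-predicted expectation `e(i→j) ∝ pᵢpⱼ`,
  compared by the chi-square distance Σ(o−e)²/e with a 5000-draw
  observed/expected swap permutation test.
- **Group statistics** — log-transform, ANCOVA with age, sex, education
  and five medication flags as covariates, Benjamini–Hochberg FDR over
  the 24-feature battery, gated pairwise post hoc contrasts, partial
  correlation.
- **Classification** — z-scored features, PCA retaining 99% variance,
  leave-one-out cross-validated multinomial/logistic regression, LDA,
  QDA or RBF SVM (fold-internal preprocessing by default).
- **Synthetic cohorts** — a semi-Markov generator with gamma dwell times,
  a 10 Hz rectified-sinusoid GFP envelope, controllable SNR, per-group
  dwell offsets and realistic covariate marginals, so every stage is
  testable by parameter recovery.

## Worked example

Simulate a 24-subject cohort (HC/MCI/AD) in which the MCI and AD groups
have a planted +15 ms mean dwell on map A, then run the whole pipeline:

```r
library(microstatr)

base <- subject_sim_config(duration_s = 30, snr = 8)
groups <- list(
  list(name = "HC",  n = 8, dwell_offset_ms = rep(0, 4)),
  list(name = "MCI", n = 8, dwell_offset_ms = c(15, 0, 0, 0)),
  list(name = "AD",  n = 8, dwell_offset_ms = c(15, 0, 0, 0)))
cfg <- pipeline_config(
  cohort_sim_config(groups, base_cfg = base, seed = 42),
  peaks_per_subject = 500, n_restarts = 20, n_permutations = 1000,
  classifiers = "multinomial", master_seed = 42)
res <- run_pipeline(cfg)
res
#> Microstate pipeline result: 24 subjects, bands: broadband
#>   primary-band mean GEV: 0.962
#>   syntax permutation p = 0.9700
#>   multinomial LOO accuracy: 54.2%

res$bands$broadband$maps$labels            # canonical labels of the 4 maps
#> [1] "A" "B" "C" "D"
round(res$bands$broadband$maps$assignment_corr, 3)
#> [1] 1 1 1 1                              # |corr| with the planted templates

gs <- res$group_stats
gs[gs$significant, c("feature", "F", "p", "p_fdr")]
#>        feature        F           p      p_fdr
#>    duration_m1 9.430886 0.001968631 0.04724713
#>    coverage_m1 7.896346 0.004114730 0.04769879
#>  trans_A_D_pct 7.176192 0.005962349 0.04769879

a <- which(res$bands$broadband$maps$assignment == 1)  # cluster labeled A
round(tapply(res$features[[paste0("duration_m", a)]],
             res$features$group, mean), 1)
#>    AD    HC   MCI
#>  99.9  88.4 103.5
```

Reading the output: the four global maps recovered from GFP-peak
clustering match the planted templates exactly (spatial |correlation| 1.0
and canonical labels A–D); the ANCOVA + FDR battery flags the duration and
coverage of map A — the planted group effect — at `p_fdr < .05`; mean map-A
duration is ~88 ms in HC versus ~100–104 ms in MCI/AD (durations sit above
the planted 75/90 ms means because 30 ms smoothing removes short
segments, identically in all groups).  The syntax permutation p of 0.97 is
expected here: the simulated transition matrix is uniform, i.e. syntax is
exactly occurrence-random.

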