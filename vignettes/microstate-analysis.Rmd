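---
title: "Microstate analysis of resting-state EEG: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate analysis of resting-state EEG: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstatr)
```

## The model

Resting-state EEG can be described as a sequence of *microstates*: brief
(roughly 60–120 ms) periods during which the scalp potential topography
stays quasi-stable before switching to another configuration.  A small set
of recurring topographies — canonically labeled A (lateralized diagonal),
B (its left–right mirror image), C (antero-posterior) and D
(fronto-central) — accounts for most of the signal.  `microstatr`
implements the standard segmentation pipeline for 19-channel 10–20
recordings and the group statistics built on top of it, together with a
synthetic cohort generator that plants known microstate structure so that
every stage can be validated by parameter recovery.

The measurement chain is:

1. **Global field power (GFP).**  For an average-referenced frame
   $v \in \mathbb{R}^{C}$, $\mathrm{GFP}(v) = \sqrt{\tfrac1C \sum_c (v_c -
   \bar v)^2}$.  GFP maxima are the moments of highest topographic
   signal-to-noise; only these frames enter clustering.
2. **Peak extraction.**  Local GFP maxima are detected within 1-s epochs
   (never across epoch boundaries), with a minimum spacing of 10 ms — on a
   conflict the higher peak wins.  Peaks whose GFP exceeds a threshold
   computed over all detected peaks are excluded as outliers; the first
   1000 surviving peaks (temporal order) are kept per subject.
3. **Modified K-means.**  Peak topographies from all subjects are pooled
   (capped per subject, equalizing contributions) and clustered ignoring
   polarity: frame $x_i$ is assigned to the map $m_k$ maximizing
   $(x_i^\top m_k)^2$, and each map is updated to the dominant eigenvector
   of $\sum_{i \in k} x_i x_i^\top$.  The best of 50 random restarts (by
   residual variance) is kept; the iteration cap is 1000.
4. **Back-fitting and smoothing.**  Every sample of the recording is
   labeled with the map of maximal squared spatial correlation (polarity
   ignored), then segments shorter than 30 ms are rejected: their samples
   are reassigned, per sample, to whichever flanking run's map fits
   better.
5. **Statistics.**  Per map: *duration* (mean segment length, ms),
   *occurrence* (segment onsets per second), *coverage* (percent of
   samples); plus *GEV*, the GFP²-weighted fraction of topographic
   variance explained by the assigned maps,
   $\mathrm{GEV} = \sum_t \mathrm{GFP}_t^2\, \rho_t^2 \big/ \sum_t
   \mathrm{GFP}_t^2$ with $\rho_t$ the spatial correlation between frame
   $t$ and its assigned map.
6. **Syntax.**  Observed transition percentages over the 12 ordered map
   pairs are compared with the percentages predicted from occurrence
   alone, $e_{i \to j} \propto p_i p_j$ ($i \neq j$), via the chi-square
   distance $\sum (o-e)^2/e$ and a permutation test that randomly swaps
   each subject's observed/expected pair.
7. **Group statistics.**  Features are log-transformed, compared across
   groups by ANCOVA (age, sex, education and five medication flags as
   covariates), corrected by Benjamini–Hochberg FDR over the 24-feature
   battery (12 map features + 12 transitions), with pairwise GLM post hoc
   contrasts only after a feature survives FDR.
8. **Classification.**  Per-subject features are z-scored, compressed by
   PCA retaining 99% of variance, and diagnosis is predicted by
   leave-one-out cross-validation (multinomial or logistic regression,
   LDA, QDA, or an RBF SVM).

## Parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `k` | 4 | maps | the reproducible canonical set; 3/5/6 supported |
| `min_peak_distance_ms` | 10 | ms | prevents double-counting one GFP hump |
| `peaks_per_subject` | 1000 | peaks | equalizes subject contributions |
| `sd_threshold` | 2 | SDs | excludes artifact-scale GFP outliers |
| `smoothing_ms` | 30 | ms | rejects noise-scale segments |
| `n_restarts` | 50 | restarts | escapes K-means local minima |
| `n_permutations` | 5000 | draws | syntax-test resolution (~2·10⁻⁴) |
| `retained_variance` | 0.99 | fraction | PCA compression before regression |

The GFP-outlier rule is stated ambiguously in the literature ("exceeded two
times the standard deviation"); `extract_gfp_peaks()` defaults to
*mean + 2 SD of the peak GFPs* and exposes the literal *2 SD* reading via
`exclude_rule = "2sd"`.

## The synthetic generator

`simulate_subject()` draws a hidden semi-Markov path over the K template
maps: dwell times are gamma distributed per map (shape 2, configurable
means, default 75/80/85/100 ms), and the next state is drawn from a
row-normalized transition-weight matrix.  The active map is emitted under a
rectified-sinusoid envelope $|\sin 2\pi f t|$ with $f = 10$ Hz, producing
discrete GFP peaks at twice the carrier frequency — the peak density the
method expects from alpha-dominant resting EEG.  White sensor noise is
scaled so that the state-signal RMS over noise RMS equals `snr`, and the
frames are average-referenced.  An explicit semi-Markov chain (rather than
a first-order Markov chain) lets mean dwell (duration) and transition
structure be planted independently, which is what the group statistics
need to be tested against.

`simulate_cohort()` adds per-group additive offsets on the per-map mean
dwell (default: +15 ms on map A in the MCI and AD groups, none in HC) and
draws covariates from per-group marginals typical of an elderly
memory-clinic cohort (HC/MCI/AD ages ≈ 66/70/75 ± 8 years, education
≈ 14/12/10 years, about 55–60% female, sparse medication flags,
MMSE ≈ 29/27/24).  Covariates are independent of the EEG given group
membership — the simplest model that still exercises covariate adjustment.

What the generator deliberately does **not** emulate: 1/f background
spectra, spatially correlated sensor noise, ocular/cardiac artifacts,
eyes-open segments, drowsiness drift, inter-subject topographic
variability, or any amplitude calibration in microvolts (all downstream
statistics are scale-invariant, so units are arbitrary).  Passing the
recovery tests therefore shows that the *algorithms* are correct and well
calibrated under the stated noise model — not that the pipeline is robust
to every artifact structure of clinical EEG.

## Numerical and design choices

- **Filtering.**  Zero-phase windowed-sinc FIR with a Kaiser window; beta
  follows from the maximum passband ripple (0.001) and the order from the
  Kaiser design formula with a transition width of 25% of the lowest edge.
  The realized order is recorded on the filtered object.  Filters are
  applied forward with group-delay compensation, so segment timing is not
  shifted.
- **Delta band.**  Realized as a pure lowpass below 4 Hz (no 1 Hz high-pass
  edge), following the analysis procedure rather than the band's name.
- **Epoch discontinuity.**  Peaks, runs and transitions never span epoch
  boundaries (epochs of cleaned clinical EEG are discontinuous after
  artifact rejection).  Edge-truncated runs are included in the duration
  average by default (`include_edge_runs = FALSE` excludes them); with
  them included, coverage = duration × occurrence / 10 holds exactly.
- **Ties and degeneracies.**  Back-fitting ties go to the lowest map
  index; an empty K-means cluster is reseeded from the worst-fitting
  topography (keeping K fixed); a zero-SD peak set disables the outlier
  rule; an all-zero frame gets fit 0.
- **Smoothing rule.**  The toolbox-internal reassignment rule for sub-30 ms
  segments is not printed anywhere authoritative; ours reassigns each
  sample of a short run to the better-fitting flanking map, one shortest
  run at a time with run boundaries recomputed after every fix, and is
  tested for idempotence on clean segmentations.
- **Expected transitions.**  The occurrence product rule
  $e_{i\to j} \propto p_i p_j$ is the default; the row-conditional variant
  $e_{i\to j} \propto p_i p_j/(1-p_i)$ is available
  (`rule = "row-conditional"`) for sensitivity analysis.  The permutation
  statistic is computed on across-subject *mean* vectors, and p-values use
  the add-one convention, so p = 0 is impossible.
- **ANCOVA.**  The group factor is tested by Type II sums of squares (the
  increment over the covariate-only model); zero-variance covariates are
  dropped, reducing to one-way ANOVA.  Complete cases only.  GEV is
  compared with the same ANCOVA but sits outside the 24-feature FDR
  battery, mirroring its separate reporting convention.
- **Zero transition percentages** (possible in short recordings) are
  offset by half the smallest positive observed value before the log, and
  flagged on the returned table.
- **Leakage.**  Z-scoring and PCA are fitted inside each LOO training fold
  by default; `paper_mode = TRUE` fits them once on the full matrix for
  comparison with analyses that do not refit per fold.  PCA is applied for
  multinomial/logistic/QDA and skipped for LDA and SVM; the SVM runs a
  small inner 5-fold grid search over cost {1, 10, 100} and gamma
  {0.1, 1, 10}/p.
- **Feature keying.**  Band-specific maps can earn hybrid labels (e.g.
  "A/B") when their top two template correlations differ by < 0.05, so
  features are keyed by cluster index (`duration_m1`, …) with canonical
  letters kept as metadata.
- **Peaks per subject.**  1000 by default; reported analyses sometimes
  truncate further (e.g. to the first 534 peaks) to equalize recording
  lengths — the cap is a single exposed parameter.
- **Determinism.**  Every stochastic stage takes a seed; the pipeline
  derives child seeds from one master seed, so identical configurations
  reproduce bit-identical results (the SVM's inner CV splits are the only
  seed-dependent part of the classifiers).

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle where
one exists: the clustering objective against brute-force enumeration of
all polarity-invariant assignments (n ≤ 10, K = 2, 50 instances), BH
adjustment against a hand-computed step-up oracle, expected transitions
against hand arithmetic and enumeration, and the statistics against exact
hand-counted label sequences.  Parameter recovery runs use a 12-subject
cohort (60 s per subject, SNR 8) for map recovery, and 50 seeded cohorts
of 3 × 30 subjects (20 s per subject, 300 peaks and 10 restarts per
cohort) for the dwell-effect recovery and false-positive-control checks —
sizes chosen so the whole suite runs at desk scale; null-cohort feature
batteries are computed from the generator's ground-truth label paths.
Syntax calibration uses 200 null replicates of 30 subjects with 1000
permutations; chance-level classification uses 100 label-permuted
replicates of 45 subjects.  The acceptance script analyzes one simulated
3 × 20-subject cohort (60 s per subject) at the full defaults
(1000 peaks, 50 restarts, 5000 permutations).

## Known limitations

- Global maps are cohort-level; per-subject individual segmentation is
  out of scope.
- No head-model forward simulation: synthetic topographies are geometric
  stand-ins, not biophysical dipole fields.
- Noise is spatially white after average referencing; spatially
  correlated noise is not modeled.
- EDF ingestion is not provided; recordings enter as numeric matrices
  (channels × samples) plus a sampling rate and montage.
- Smoothing inflates short-dwell durations (every surviving segment is at
  least 30 ms), so recovered durations sit above the planted means; group
  *differences* are preserved, which is what the statistics consume.
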