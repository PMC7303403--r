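# Build an epoched object whose GFP trace equals |g| exactly, using the
# two-channel antisymmetric frame (g, -g).
epochs_from_gfp <- function(g, fs = 200) {
  epoch_recording(recording(rbind(g, -g), fs, c("a", "b")), 1)
}

test_that("gfp matches the hand-computed spatial standard deviation", {
  expect_equal(gfp(c(1, -1, rep(0, 17))), sqrt(2 / 19))
  expect_equal(gfp(rep(3.7, 19)), 0)
  v <- rnorm(19)
  expect_equal(gfp(-2.5 * v), 2.5 * gfp(v))
  expect_error(gfp(1), ">= 2 channels")
})

test_that("minimum peak distance keeps the higher of two close peaks", {
  g <- rep(0.1, 200)
  g[21] <- 1; g[23] <- 0.8; g[101] <- 0.9
  ep <- epochs_from_gfp(g)
  # 15 ms = 3 samples at 200 Hz: the 0.8 peak is too close to the 1.0 peak
  pk <- extract_gfp_peaks(ep, min_distance_ms = 15, sd_threshold = 100)
  expect_identical(pk$sample, c(21L, 101L))
  # at the default 10 ms (2 samples) the spacing is legal and both survive
  pk2 <- extract_gfp_peaks(ep, min_distance_ms = 10, sd_threshold = 100)
  expect_identical(pk2$sample, c(21L, 23L, 101L))
})

test_that("peak density of the rectified-sinusoid envelope is ~2 per cycle", {
  cfg <- subject_sim_config(carrier_freq_hz = 10, duration_s = 60, snr = 100)
  sim <- simulate_subject(cfg, seed = 2)
  ep <- epoch_recording(sim$recording, 1)
  pk <- extract_gfp_peaks(ep, max_peaks = 5000)
  expect_lt(abs(nrow(pk$topographies) - 1200) / 1200, 0.10)
})

test_that("identical peak heights disable the SD exclusion rule", {
  g1 <- rep(0.1, 200)
  g1[seq(5, 195, by = 10)] <- 1  # 20 exactly equal peaks per epoch
  ep <- epochs_from_gfp(rep(g1, 3))
  pk <- extract_gfp_peaks(ep, max_peaks = 5000)
  expect_equal(unname(stats::sd(pk$gfp_values)), 0)
  expect_identical(nrow(pk$topographies), 60L)  # none excluded
})

test_that("peak extraction truncates to the first max_peaks in time order", {
  cfg <- subject_sim_config(duration_s = 10, snr = 50)
  sim <- simulate_subject(cfg, seed = 3)
  ep <- epoch_recording(sim$recording, 1)
  all_pk <- extract_gfp_peaks(ep, max_peaks = 5000)
  few <- extract_gfp_peaks(ep, max_peaks = 50)
  expect_identical(nrow(few$topographies), 50L)
  expect_identical(few$sample, all_pk$sample[1:50])
  expect_true(all(diff(few$epoch * 10000 + few$sample) > 0))
})

test_that("modified K-means recovers degenerate and planted structure", {
  # all topographies equal up to polarity: one map, zero residual
  v <- rnorm(8); v <- v - mean(v)
  x <- rbind(v, -v, v, v, -v)
  km <- modified_kmeans(x, 1, restarts = 5, seed = 1)
  expect_equal(abs(spatial_correlation(km$maps[1, ], v)), 1,
               tolerance = 1e-9)
  expect_equal(km$residual, 0, tolerance = 1e-9)

  # 12 topographies = +-(4 orthogonal maps) + tiny noise
  set.seed(4)
  q <- qr.Q(qr(scale(matrix(rnorm(19 * 4), 19, 4), scale = FALSE)))
  maps <- t(q)
  signs <- rep(c(1, -1, 1), 4)
  x <- maps[rep(1:4, each = 3), ] * signs + 1e-4 * rnorm(12 * 19)
  km <- modified_kmeans(x, 4, restarts = 20, seed = 2)
  cmat <- abs(cor(t(km$maps), t(maps)))
  best <- apply(cmat, 1, max)
  expect_gt(min(best), 0.99)
})

test_that("modified K-means attains the brute-force optimum (small cases)", {
  for (s in 1:5) {
    set.seed(100 + s)
    x <- random_topographies(8, 4)
    km <- modified_kmeans(x, 2, restarts = 50, seed = s)
    oracle <- brute_force_kmeans_residual(x, 2)
    expect_equal(km$residual, oracle, tolerance = 1e-8)
  }
  expect_error(modified_kmeans(random_topographies(3, 4), 5), "exceed")
})

test_that("aggregation equalizes subject contributions", {
  cfg <- subject_sim_config(duration_s = 10)
  sim <- simulate_subject(cfg, seed = 6)
  ep <- epoch_recording(sim$recording, 1)
  pk <- extract_gfp_peaks(ep, max_peaks = 100)
  one <- aggregate_and_cluster(list(pk), k = 4, restarts = 10, seed = 9)
  alone <- modified_kmeans(pk$topographies, 4, restarts = 10, seed = 9)
  expect_equal(one$residual, alone$residual, tolerance = 1e-9)
  # duplicated subject: same subspace recovered (compare up to polarity)
  two <- aggregate_and_cluster(list(pk, pk), k = 4, restarts = 10, seed = 9)
  cmat <- abs(cor(t(two$maps), t(one$maps)))
  expect_gt(min(apply(cmat, 1, max)), 0.999)
})

test_that("canonical labeling is exact, permutation-equivariant and hybrid-aware", {
  tm <- make_canonical_maps()
  ms <- structure(list(maps = tm$maps, labels = as.character(1:4),
                       montage = tm$montage, polarity_ambiguous = TRUE),
                  class = "microstate_maps")
  lab <- assign_canonical_labels(ms, tm)
  expect_identical(lab$labels, c("A", "B", "C", "D"))
  expect_equal(unname(lab$assignment_corr), rep(1, 4), tolerance = 1e-12)

  shuffle <- c(3, 1, 4, 2)
  ms2 <- ms; ms2$maps <- tm$maps[shuffle, ] * c(1, -1, 1, -1)  # polarity too
  lab2 <- assign_canonical_labels(ms2, tm)
  expect_identical(lab2$labels, c("C", "A", "D", "B"))

  hybrid <- microstatr:::.avg_ref_unit(tm$maps["A", ] + tm$maps["B", ])
  ms3 <- ms; ms3$maps[1, ] <- hybrid
  lab3 <- assign_canonical_labels(ms3, tm)
  expect_match(lab3$labels[1], "^[AB]/[AB]$")

  expect_warning(assign_canonical_labels(
    structure(list(maps = tm$maps[1:3, ], labels = as.character(1:3),
                   montage = tm$montage), class = "microstate_maps"), tm),
    "labels left as indices")
})

test_that("back-fitting is polarity-invariant and accurate on planted data", {
  tm <- make_canonical_maps()
  ms <- structure(list(maps = tm$maps, labels = tm$labels,
                       montage = tm$montage), class = "microstate_maps")
  env <- abs(sin(2 * pi * 10 * (0:399) / 200)) + 0.05
  sig <- t(outer(env, tm$maps["C", ]))
  ep <- epoch_recording(recording(sig, 200, tm$montage), 1)
  seg <- backfit(ep, ms)
  expect_true(all(unlist(seg$labels) == 3L))
  expect_equal(mean(unlist(seg$fit)), 1, tolerance = 1e-9)
  seg_neg <- backfit(epoch_recording(recording(-sig, 200, tm$montage), 1), ms)
  expect_identical(seg_neg$labels, seg$labels)

  # planted alternating sequence at snr 8: >= 95% label accuracy at GFP peaks
  cfg <- subject_sim_config(duration_s = 30, snr = 8)
  sim <- simulate_subject(cfg, seed = 12)
  ep2 <- epoch_recording(sim$recording, 1)
  seg2 <- backfit(ep2, ms)
  pk <- extract_gfp_peaks(ep2, max_peaks = 5000)
  truth <- labels_to_epochs(sim$states, 200)
  acc <- mean(vapply(seq_along(pk$sample), function(i) {
    seg2$labels[[pk$epoch[i]]][pk$sample[i]] ==
      truth[[pk$epoch[i]]][pk$sample[i]]
  }, logical(1)))
  expect_gte(acc, 0.95)

  bad <- epoch_recording(recording(sig[1:18, ], 200, tm$montage[1:18]), 1)
  expect_error(backfit(bad, ms), "montage")
})

test_that("short-segment smoothing merges, preserves and restores labels", {
  tm <- make_canonical_maps()
  ms <- structure(list(maps = tm$maps, labels = tm$labels,
                       montage = tm$montage), class = "microstate_maps")
  # A(100 ms) B(10 ms) A(100 ms) -> one A run of 210 ms
  lab <- c(rep(1L, 20), rep(2L, 2), rep(1L, 20), rep(1L, 158))
  sig <- t(tm$maps[lab, ])
  ep <- epoch_recording(recording(sig, 200, tm$montage), 1)
  seg <- smooth_segmentation(backfit(ep, ms), 30)
  expect_true(all(seg$labels[[1]] == 1L))

  # all runs >= 30 ms: identity
  lab2 <- rep(c(1L, 2L, 3L, 4L), each = 50)
  sig2 <- t(tm$maps[lab2, ])
  ep2 <- epoch_recording(recording(sig2, 200, tm$montage), 1)
  seg2 <- backfit(ep2, ms)
  expect_identical(smooth_segmentation(seg2, 30)$labels, seg2$labels)

  # 5% single-sample label noise is repaired to >= 99% agreement
  set.seed(20)
  clean <- rep(sample(1:4, 60, replace = TRUE), each = 20)[1:1000]
  sig3 <- t(tm$maps[clean, ])
  ep3 <- epoch_recording(recording(sig3, 200, tm$montage), 1)
  seg3 <- backfit(ep3, ms)
  noisy <- seg3
  for (e in seq_along(noisy$labels)) {
    n <- length(noisy$labels[[e]])
    hit <- sample(n, round(0.05 * n))
    noisy$labels[[e]][hit] <-
      ((noisy$labels[[e]][hit] + sample(1:3, length(hit),
                                        replace = TRUE) - 1L) %% 4L) + 1L
  }
  sm <- smooth_segmentation(noisy, 30)
  agree <- mean(unlist(sm$labels) == unlist(seg3$labels))
  expect_gte(agree, 0.99)
})

test_that("microstate statistics match the worked micro-example", {
  lab <- c(rep(1L, 40), rep(2L, 60), rep(1L, 100))
  seg <- segmentation_from_labels(list(lab), fs = 200, n_maps = 2,
                                  map_labels = c("A", "B"))
  st <- compute_stats(seg)
  expect_equal(st$per_map$duration_ms, c(350, 300))
  expect_equal(st$per_map$occurrence_per_s, c(2, 1))
  expect_equal(st$per_map$coverage_pct, c(70, 30))
})

test_that("GEV is 1 on self-consistent signal; coverage partitions time", {
  tm <- make_canonical_maps()
  ms <- structure(list(maps = tm$maps, labels = tm$labels,
                       montage = tm$montage), class = "microstate_maps")
  lab <- rep(c(1L, 3L, 2L, 4L), each = 50)
  sig <- t(tm$maps[rep(lab, 3), ]) * 2.3
  ep <- epoch_recording(recording(sig, 200, tm$montage), 1)
  st <- compute_stats(smooth_segmentation(backfit(ep, ms), 30))
  expect_equal(st$gev_total, 1, tolerance = 1e-9)
  expect_equal(sum(st$per_map$coverage_pct), 100, tolerance = 1e-9)
})

test_that("never-occurring maps report missing duration, zero elsewhere", {
  lab <- rep(c(1L, 2L), each = 100)
  seg <- segmentation_from_labels(list(lab), fs = 200, n_maps = 4)
  st <- compute_stats(seg)
  expect_true(all(is.na(st$per_map$duration_ms[3:4])))
  expect_equal(st$per_map$occurrence_per_s[3:4], c(0, 0))
  expect_equal(st$per_map$coverage_pct[3:4], c(0, 0))
})

test_that("coverage equals duration x occurrence / 10 on long recordings", {
  cfg <- subject_sim_config(duration_s = 120, snr = 8)
  sim <- simulate_subject(cfg, seed = 33)
  tm <- cfg$templates
  ms <- structure(list(maps = tm$maps, labels = tm$labels,
                       montage = tm$montage), class = "microstate_maps")
  ep <- epoch_recording(sim$recording, 1)
  st <- compute_stats(smooth_segmentation(backfit(ep, ms), 30))
  with(st$per_map, expect_equal(coverage_pct,
                                duration_ms * occurrence_per_s / 10,
                                tolerance = 0.02))
})

test_that("statistics are invariant to sign flip and positive rescaling", {
  cfg <- subject_sim_config(duration_s = 20, snr = 8)
  sim <- simulate_subject(cfg, seed = 44)
  tm <- cfg$templates
  ms <- structure(list(maps = tm$maps, labels = tm$labels,
                       montage = tm$montage), class = "microstate_maps")
  run_stats <- function(data) {
    ep <- epoch_recording(recording(data, 200, tm$montage, "average"), 1)
    st <- compute_stats(smooth_segmentation(backfit(ep, ms), 30))
    list(pm = st$per_map, gev = st$gev_total)
  }
  base <- run_stats(sim$recording$data)
  flip <- run_stats(-sim$recording$data)
  scaled <- run_stats(7.3 * sim$recording$data)
  expect_equal(flip$pm, base$pm)
  expect_equal(flip$gev, base$gev)
  expect_equal(scaled$pm, base$pm)
  expect_equal(scaled$gev, base$gev)
})
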