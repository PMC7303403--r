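# Microstate segmentation: GFP peak extraction, polarity-invariant modified
# K-means over peak topographies, canonical labeling, back-fitting,
# short-segment smoothing, and per-subject microstate statistics.

#' Global field power of one frame
#'
#' The spatial standard deviation of a scalp potential vector: the root
#' mean square of the channel deviations from the instantaneous channel
#' mean.  GFP local maxima mark the moments of highest topographic
#' signal-to-noise that segmentation operates on.
#'
#' @param frame Numeric channel vector (>= 2 channels).
#' @return Nonnegative scalar.
#' @examples
#' gfp(c(1, -1, rep(0, 17)))  # sqrt(2/19)
#' @export
gfp <- function(frame) {
  if (length(frame) < 2L) stop("gfp requires >= 2 channels")
  sqrt(mean((frame - mean(frame))^2))
}

# GFP trace of a channels x samples matrix (vectorized).
gfp_trace <- function(data) {
  centered <- sweep(data, 2L, colMeans(data))
  sqrt(colMeans(centered^2))
}

# Local maxima of a vector with a minimum spacing; on conflict the higher
# peak wins (greedy by height).
.find_peaks <- function(g, min_dist) {
  n <- length(g)
  if (n < 3L) return(integer(0))
  cand <- which(g[2:(n - 1L)] > g[1:(n - 2L)] &
                g[2:(n - 1L)] >= g[3:n]) + 1L
  if (length(cand) == 0L || min_dist <= 1L) return(cand)
  ord <- cand[order(g[cand], decreasing = TRUE)]
  keep <- logical(n)
  for (i in ord) {
    lo <- max(1L, i - min_dist + 1L)
    hi <- min(n, i + min_dist - 1L)
    if (!any(keep[lo:hi])) keep[i] <- TRUE
  }
  sort(which(keep))
}

#' Extract GFP-peak topographies
#'
#' Finds local maxima of the GFP trace within each epoch (peaks never span
#' epoch boundaries), enforces a minimum peak distance (the higher peak
#' wins), excludes outlying peaks by a GFP threshold computed over all
#' detected peaks, and keeps the first `max_peaks` surviving peaks in
#' temporal order.
#'
#' @param ep An `eeg_epochs` object.
#' @param min_distance_ms Minimum distance between peaks in ms (default 10).
#' @param max_peaks Maximum number of peaks retained (default 1000).
#' @param sd_threshold Exclusion multiplier on the SD of peak GFPs
#'   (default 2).
#' @param exclude_rule `"mean+2sd"` (exclude peaks above mean + k SD of the
#'   peak GFPs, default) or `"2sd"` (above k SD).  A zero SD excludes
#'   nothing.
#' @param subject_id Optional identifier carried on the result.
#' @return A `gfp_peaks` object: `topographies` (n_peaks x channels,
#'   average-referenced frames), `gfp_values`, `epoch`, `sample` indices,
#'   `fs`, `montage`.
#' @export
extract_gfp_peaks <- function(ep, min_distance_ms = 10, max_peaks = 1000,
                              sd_threshold = 2,
                              exclude_rule = c("mean+2sd", "2sd"),
                              subject_id = NA_character_) {
  exclude_rule <- match.arg(exclude_rule)
  min_dist <- max(1L, as.integer(round(min_distance_ms * ep$fs / 1000)))
  ep_idx <- integer(0); s_idx <- integer(0); gvals <- numeric(0)
  for (k in seq_along(ep$epochs)) {
    g <- gfp_trace(ep$epochs[[k]])
    pk <- .find_peaks(g, min_dist)
    ep_idx <- c(ep_idx, rep(k, length(pk)))
    s_idx <- c(s_idx, pk)
    gvals <- c(gvals, g[pk])
  }
  if (length(s_idx) == 0L) {
    warning("no GFP peaks found")
    return(structure(list(subject_id = subject_id,
                          topographies = matrix(0, 0, length(ep$montage)),
                          gfp_values = numeric(0), epoch = integer(0),
                          sample = integer(0), fs = ep$fs,
                          montage = ep$montage),
                     class = "gfp_peaks"))
  }
  s <- stats::sd(gvals)
  keep <- if (s == 0) rep(TRUE, length(gvals)) else {
    thr <- if (exclude_rule == "mean+2sd") {
      mean(gvals) + sd_threshold * s
    } else sd_threshold * s
    gvals <= thr
  }
  ep_idx <- ep_idx[keep]; s_idx <- s_idx[keep]; gvals <- gvals[keep]
  take <- seq_len(min(max_peaks, length(s_idx)))
  ep_idx <- ep_idx[take]; s_idx <- s_idx[take]; gvals <- gvals[take]
  topo <- t(vapply(seq_along(s_idx), function(i) {
    v <- ep$epochs[[ep_idx[i]]][, s_idx[i]]
    v - mean(v)
  }, numeric(length(ep$montage))))
  colnames(topo) <- ep$montage
  structure(list(subject_id = subject_id, topographies = topo,
                 gfp_values = gvals, epoch = ep_idx, sample = s_idx,
                 fs = ep$fs, montage = ep$montage),
            class = "gfp_peaks")
}

#' @export
print.gfp_peaks <- function(x, ...) {
  cat(sprintf("GFP peaks: %d peaks x %d channels\n",
              nrow(x$topographies), ncol(x$topographies)))
  invisible(x)
}

# One K-means restart from given initial maps.  Assignment maximizes the
# squared projection (polarity-invariant); the update sets each map to the
# dominant eigenvector of the scatter of its assigned topographies.
.mkmeans_once <- function(x, k, init_maps, max_iter, tol, total_ss) {
  m <- init_maps
  n <- nrow(x)
  resid_prev <- Inf
  assign <- integer(n)
  for (iter in seq_len(max_iter)) {
    proj2 <- (x %*% t(m))^2
    assign <- max.col(proj2, ties.method = "first")
    fitted <- proj2[cbind(seq_len(n), assign)]
    # re-seed empty clusters from the worst-fitting topography
    for (kk in which(tabulate(assign, k) == 0L)) {
      worst <- which.max(rowSums(x^2) - fitted)
      v <- x[worst, ]
      m[kk, ] <- v / sqrt(sum(v^2))
      assign[worst] <- kk
      fitted[worst] <- sum(v^2)
    }
    for (kk in seq_len(k)) {
      idx <- which(assign == kk)
      s <- crossprod(x[idx, , drop = FALSE])
      ev <- eigen(s, symmetric = TRUE)$vectors[, 1L]
      m[kk, ] <- ev / sqrt(sum(ev^2))
    }
    proj2 <- (x %*% t(m))^2
    assign <- max.col(proj2, ties.method = "first")
    resid <- total_ss - sum(proj2[cbind(seq_len(n), assign)])
    if (is.finite(resid_prev) &&
        abs(resid_prev - resid) <= tol * max(resid_prev, .Machine$double.eps)) {
      resid_prev <- resid
      break
    }
    resid_prev <- resid
  }
  list(maps = m, assign = assign, residual = resid_prev, n_iter = iter)
}

#' Polarity-invariant modified K-means clustering of topographies
#'
#' Clusters scalp topographies ignoring polarity: each topography is
#' assigned to the map maximizing its squared projection, and each map is
#' updated to the dominant eigenvector of the scatter matrix of its
#' assigned topographies.  The best of `restarts` random restarts (initial
#' maps drawn from the data) by residual variance is returned.
#'
#' @param x n x channels matrix of average-referenced topographies.
#' @param k Number of maps (2 <= k <= n).
#' @param restarts Number of random restarts (default 50).
#' @param max_iter Maximum iterations per restart (default 1000).
#' @param tol Relative residual-change stopping tolerance (default 1e-7).
#' @param seed Integer seed for reproducible restarts.
#' @param montage Optional channel labels carried on the result.
#' @return A `microstate_maps` object: `maps` (k x channels, zero-mean
#'   unit-norm rows), `labels` (cluster indices until canonical labeling),
#'   `residual`, `r2` (fraction of total squared amplitude explained),
#'   `assignments`, `polarity_ambiguous = TRUE`.
#' @export
modified_kmeans <- function(x, k, restarts = 50, max_iter = 1000,
                            tol = 1e-7, seed = NULL, montage = colnames(x)) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k must not exceed the number of topographies")
  if (k < 1L) stop("k must be positive")
  total_ss <- sum(x^2)
  .with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      init_idx <- sample.int(n, k)
      init <- x[init_idx, , drop = FALSE]
      nrm <- sqrt(rowSums(init^2))
      nrm[nrm == 0] <- 1
      init <- init / nrm
      res <- .mkmeans_once(x, k, init, max_iter, tol, total_ss)
      if (is.null(best) || res$residual < best$residual) best <- res
    }
    maps <- best$maps
    # dominant eigenvectors of average-referenced data are zero-mean up to
    # numerical error; enforce exactly and renormalize
    maps <- maps - rowMeans(maps)
    maps <- maps / sqrt(rowSums(maps^2))
    colnames(maps) <- montage
    structure(list(maps = maps, labels = as.character(seq_len(k)),
                   montage = montage, residual = best$residual,
                   r2 = 1 - best$residual / total_ss,
                   assignments = best$assign, n_iter = best$n_iter,
                   polarity_ambiguous = TRUE),
              class = "microstate_maps")
  })
}

#' @export
print.microstate_maps <- function(x, ...) {
  cat(sprintf("Microstate maps: K = %d (%s), R^2 = %.3f\n",
              nrow(x$maps), paste(x$labels, collapse = ", "), x$r2))
  invisible(x)
}

#' Aggregate peak topographies across subjects and cluster
#'
#' Concatenates up to `peaks_per_subject` GFP-peak topographies per subject
#' (equalizing contributions across subjects) and runs one modified K-means
#' on the pooled set, producing the cohort-level global maps.
#'
#' @param peaks_list List of `gfp_peaks` objects, one per subject.
#' @param k Number of maps (default 4).
#' @param peaks_per_subject Per-subject cap on contributed peaks
#'   (default 1000).
#' @param ... Passed to [modified_kmeans()] (`restarts`, `max_iter`, `tol`,
#'   `seed`).
#' @return A `microstate_maps` object (the global maps).
#' @export
aggregate_and_cluster <- function(peaks_list, k = 4, peaks_per_subject = 1000,
                                  ...) {
  if (length(peaks_list) < 1L) stop("at least one subject is required")
  mats <- lapply(peaks_list, function(p) {
    utils::head(p$topographies, peaks_per_subject)
  })
  x <- do.call(rbind, mats)
  modified_kmeans(x, k, montage = peaks_list[[1L]]$montage, ...)
}

# All permutations of 1..n (n small).
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' Assign canonical labels to clustered maps
#'
#' Matches clustered maps to template maps by the one-to-one assignment
#' maximizing total absolute spatial correlation (exhaustive over the K!
#' permutations).  A map whose top two template correlations differ by less
#' than `hybrid_margin` receives a hybrid label such as `"A/B"` (letters in
#' decreasing correlation order).
#'
#' @param ms A `microstate_maps` object with K maps.
#' @param templates A `template_maps` object with K templates.
#' @param hybrid_margin Correlation-gap threshold for hybrid labels
#'   (default 0.05).
#' @return The `microstate_maps` object with `labels`,
#'   `assignment` (template index per map) and `assignment_corr` filled in.
#' @export
assign_canonical_labels <- function(ms, templates, hybrid_margin = 0.05) {
  k <- nrow(ms$maps)
  if (k != nrow(templates$maps)) {
    warning("map count differs from template count; labels left as indices")
    return(ms)
  }
  cmat <- abs(stats::cor(t(ms$maps), t(templates$maps)))  # k x k
  perms <- .permutations(k)
  scores <- apply(perms, 1L, function(p) sum(cmat[cbind(seq_len(k), p)]))
  p <- perms[which.max(scores), ]
  labels <- character(k)
  for (i in seq_len(k)) {
    ord <- order(cmat[i, ], decreasing = TRUE)
    top2 <- cmat[i, ord[1:2]]
    primary <- templates$labels[p[i]]
    if (diff(range(top2)) < hybrid_margin) {
      other <- setdiff(templates$labels[ord[1:2]], primary)[1]
      labels[i] <- paste(primary, other, sep = "/")
    } else {
      labels[i] <- primary
    }
  }
  ms$labels <- labels
  ms$assignment <- p
  ms$assignment_corr <- cmat[cbind(seq_len(k), p)]
  ms
}

#' Back-fit global maps to an epoched recording
#'
#' Labels every sample with the map of maximal squared spatial correlation
#' (polarity ignored; ties broken toward the lowest map index) and stores
#' the per-sample fit with every map, the assigned fit, and the GFP trace.
#'
#' @param ep An `eeg_epochs` object with the same montage as `maps`.
#' @param maps A `microstate_maps` object.
#' @return A `segmentation` object: per-epoch `labels` (map indices), `fit`
#'   (assigned squared correlation), `fit_all` (K x samples matrices),
#'   `gfp`, plus `fs`, `n_maps`, `map_labels`.
#' @export
backfit <- function(ep, maps) {
  if (!identical(toupper(ep$montage), toupper(maps$montage)))
    stop("montage of recording and maps do not match")
  k <- nrow(maps$maps)
  labels <- vector("list", length(ep$epochs))
  fit <- vector("list", length(ep$epochs))
  fit_all <- vector("list", length(ep$epochs))
  gfp_l <- vector("list", length(ep$epochs))
  for (e in seq_along(ep$epochs)) {
    d <- sweep(ep$epochs[[e]], 2L, colMeans(ep$epochs[[e]]))
    proj <- maps$maps %*% d          # k x n
    norm2 <- colSums(d^2)
    f <- sweep(proj^2, 2L, pmax(norm2, .Machine$double.eps), "/")
    f[, norm2 == 0] <- 0
    lab <- max.col(t(proj^2), ties.method = "first")
    labels[[e]] <- lab
    fit[[e]] <- f[cbind(lab, seq_along(lab))]
    fit_all[[e]] <- f
    gfp_l[[e]] <- gfp_trace(ep$epochs[[e]])
  }
  structure(list(labels = labels, fit = fit, fit_all = fit_all,
                 gfp = gfp_l, fs = ep$fs, n_maps = k,
                 map_labels = maps$labels),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("Segmentation: %d epochs, K = %d maps @ %g Hz\n",
              length(x$labels), x$n_maps, x$fs))
  invisible(x)
}

#' Reject microstate segments shorter than a minimum duration
#'
#' Iteratively reassigns the samples of every maximal run shorter than
#' `min_duration_ms` to whichever of the two flanking runs' maps fits each
#' sample better (per-sample squared correlation); an edge run with a
#' single neighbor is absorbed by it.  Runs never merge across epoch
#' boundaries.  Iteration stops when no short run remains or after
#' `max_pass` sweeps.
#'
#' @param seg A `segmentation` from [backfit()].
#' @param min_duration_ms Minimum segment duration in ms (default 30).
#' @param max_pass Sweep cap (default 20).
#' @return The smoothed `segmentation`.
#' @export
smooth_segmentation <- function(seg, min_duration_ms = 30, max_pass = 20) {
  min_samples <- as.integer(round(min_duration_ms * seg$fs / 1000))
  if (min_samples <= 1L) return(seg)
  for (e in seq_along(seg$labels)) {
    lab <- seg$labels[[e]]
    f <- seg$fit_all[[e]]
    # fix one shortest run at a time so run boundaries are always current
    cap <- max_pass * length(lab)
    for (pass in seq_len(cap)) {
      r <- rle(lab)
      if (length(r$lengths) <= 1L) break
      short <- which(r$lengths < min_samples)
      if (length(short) == 0L) break
      si <- short[which.min(r$lengths[short])]
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      cand <- unique(c(if (si > 1L) r$values[si - 1L],
                       if (si < length(r$values)) r$values[si + 1L]))
      cand <- setdiff(cand, r$values[si])
      idx <- starts[si]:ends[si]
      if (length(cand) == 1L) {
        lab[idx] <- cand
      } else {
        lab[idx] <- cand[max.col(t(f[cand, idx, drop = FALSE]),
                                 ties.method = "first")]
      }
    }
    seg$labels[[e]] <- lab
    seg$fit[[e]] <- f[cbind(lab, seq_along(lab))]
  }
  seg
}

#' Per-subject microstate statistics
#'
#' Computes, per map: mean segment duration (ms), occurrence (segment
#' onsets per second of labeled time) and coverage (percent of samples);
#' plus the total global explained variance, the GFP^2-weighted fraction of
#' topographic variance explained by the assigned maps over all samples.
#' Runs are counted within epochs only.
#'
#' @param seg A smoothed `segmentation`.
#' @param include_edge_runs Include epoch-edge (possibly truncated) runs in
#'   the duration average (default TRUE).
#' @return A `microstate_stats` object: `per_map` data.frame (map,
#'   duration_ms, occurrence_per_s, coverage_pct) and `gev_total`.  A map
#'   that never occurs has `duration_ms = NA`, occurrence 0, coverage 0.
#' @export
compute_stats <- function(seg, include_edge_runs = TRUE) {
  k <- seg$n_maps
  run_len <- vector("list", length(seg$labels))
  run_val <- vector("list", length(seg$labels))
  total_samples <- 0L
  cover <- numeric(k)
  for (e in seq_along(seg$labels)) {
    lab <- seg$labels[[e]]
    total_samples <- total_samples + length(lab)
    cover <- cover + tabulate(lab, k)
    r <- rle(lab)
    lens <- r$lengths; vals <- r$values
    if (!include_edge_runs && length(lens) > 2L) {
      keep <- 2:(length(lens) - 1L)
      lens <- lens[keep]; vals <- vals[keep]
    }
    run_len[[e]] <- lens
    run_val[[e]] <- vals
  }
  lens <- unlist(run_len); vals <- unlist(run_val)
  total_s <- total_samples / seg$fs
  duration <- occurrence <- numeric(k)
  for (kk in seq_len(k)) {
    lk <- lens[vals == kk]
    duration[kk] <- if (length(lk)) mean(lk) * 1000 / seg$fs else NA_real_
    occurrence[kk] <- sum(vals == kk) / total_s
  }
  g <- unlist(seg$gfp)
  f <- unlist(seg$fit)
  gev <- sum(g^2 * f) / sum(g^2)
  per_map <- data.frame(map = seg$map_labels,
                        duration_ms = duration,
                        occurrence_per_s = occurrence,
                        coverage_pct = 100 * cover / total_samples,
                        stringsAsFactors = FALSE)
  structure(list(per_map = per_map, gev_total = gev,
                 total_time_s = total_s),
            class = "microstate_stats")
}

#' @export
print.microstate_stats <- function(x, ...) {
  print(x$per_map, row.names = FALSE)
  cat(sprintf("GEV = %.4f over %.1f s\n", x$gev_total, x$total_time_s))
  invisible(x)
}

#' Build a segmentation from known labels
#'
#' Constructs a `segmentation` object directly from per-sample map labels,
#' e.g. a simulator's ground-truth state path, so that duration/occurrence/
#' coverage and transition statistics can be computed for a known sequence.
#' GFP and fit default to 1 (uniform weighting) when not supplied.
#'
#' @param labels_per_epoch List of integer label vectors, one per epoch.
#' @param fs Sampling rate in Hz.
#' @param n_maps Number of maps.
#' @param map_labels Map label names.
#' @param gfp_per_epoch,fit_per_epoch Optional per-epoch GFP / fit vectors.
#' @return A `segmentation` object.
#' @export
segmentation_from_labels <- function(labels_per_epoch, fs, n_maps,
                                     map_labels = as.character(seq_len(n_maps)),
                                     gfp_per_epoch = NULL,
                                     fit_per_epoch = NULL) {
  if (is.null(gfp_per_epoch))
    gfp_per_epoch <- lapply(labels_per_epoch, function(l) rep(1, length(l)))
  if (is.null(fit_per_epoch))
    fit_per_epoch <- lapply(labels_per_epoch, function(l) rep(1, length(l)))
  structure(list(labels = labels_per_epoch, fit = fit_per_epoch,
                 fit_all = NULL, gfp = gfp_per_epoch, fs = fs,
                 n_maps = n_maps, map_labels = map_labels),
            class = "segmentation")
}
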