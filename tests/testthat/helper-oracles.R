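# Independent oracles and small simulation helpers shared by the tests.

# Brute-force optimum of the polarity-invariant clustering objective:
# enumerate every assignment of n topographies to k clusters; for a fixed
# assignment the optimal map of a cluster is the dominant eigenvector of its
# scatter matrix, so the explained sum is the top eigenvalue.  Returns the
# minimum residual over all assignments.
brute_force_kmeans_residual <- function(x, k) {
  n <- nrow(x)
  total <- sum(x^2)
  best <- Inf
  for (code in 0:(k^n - 1)) {
    a <- integer(n)
    c0 <- code
    for (i in seq_len(n)) {
      a[i] <- c0 %% k + 1L
      c0 <- c0 %/% k
    }
    expl <- 0
    for (kk in seq_len(k)) {
      idx <- which(a == kk)
      if (length(idx)) {
        s <- crossprod(x[idx, , drop = FALSE])
        expl <- expl + eigen(s, symmetric = TRUE,
                             only.values = TRUE)$values[1L]
      }
    }
    if (total - expl < best) best <- total - expl
  }
  best
}

# Random average-referenced topographies.
random_topographies <- function(n, channels) {
  x <- matrix(rnorm(n * channels), n, channels)
  x - rowMeans(x)
}

# A small cohort simulation config used across tests.
small_cohort_cfg <- function(n_per_group = c(HC = 6, MCI = 6, AD = 6),
                             offset_a_ms = 15, duration_s = 20, snr = 8,
                             seed = 1) {
  base <- subject_sim_config(duration_s = duration_s, snr = snr)
  groups <- lapply(names(n_per_group), function(g) {
    off <- if (g == "HC") rep(0, 4) else c(offset_a_ms, 0, 0, 0)
    list(name = g, n = n_per_group[[g]], dwell_offset_ms = off)
  })
  cohort_sim_config(groups, base_cfg = base, seed = seed)
}

# Split a per-sample label vector into 1-s epochs (for ground-truth paths).
labels_to_epochs <- function(states, fs) {
  n_ep <- length(states) %/% fs
  lapply(seq_len(n_ep), function(k) states[((k - 1) * fs + 1):(k * fs)])
}

# Per-subject observed/expected transition profiles drawn directly from the
# occurrence product-rule model: occurrence probabilities from a Dirichlet,
# expected from the product rule, observed as a multinomial draw around the
# expected vector (so the null of random syntax holds exactly in mean).
simulate_null_profiles <- function(n_subjects, n_transitions = 500,
                                   attractor = NULL) {
  k <- 4
  obs <- matrix(0, n_subjects, k * (k - 1))
  exp <- matrix(0, n_subjects, k * (k - 1))
  for (i in seq_len(n_subjects)) {
    p <- rgamma(k, shape = 10)
    p <- p / sum(p)
    e <- expected_transitions(p, LETTERS[1:4])
    probs <- e / 100
    if (!is.null(attractor)) {
      # multiply transitions into map `attractor` by 2 and renormalize
      into <- grepl(paste0("_to_", attractor, "$"), names(e))
      probs[into] <- 2 * probs[into]
      probs <- probs / sum(probs)
    }
    counts <- as.numeric(rmultinom(1, n_transitions, probs))
    obs[i, ] <- 100 * counts / sum(counts)
    exp[i, ] <- e
  }
  list(observed = obs, expected = exp)
}

# Gaussian 3-class feature matrices for classification tests.
simulate_class_features <- function(n_per_class = 15, n_features = 24,
                                    delta = 0) {
  classes <- c("HC", "MCI", "AD")
  y <- rep(classes, each = n_per_class)
  x <- matrix(rnorm(length(y) * n_features), length(y), n_features)
  for (ci in seq_along(classes)) {
    rows <- y == classes[ci]
    x[rows, 1:3] <- x[rows, 1:3] + delta * (ci - 1)
  }
  list(x = x, y = factor(y, levels = classes))
}
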