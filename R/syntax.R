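# Microstate syntax: observed vs occurrence-predicted transition
# percentages, chi-square distance, and the observed/expected label
# permutation test.

# Names of the K*(K-1) ordered transition pairs.
transition_pair_names <- function(map_labels) {
  k <- length(map_labels)
  out <- character(0)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    out <- c(out, paste0(map_labels[i], "_to_", map_labels[j]))
  out
}

.pair_index <- function(k) {
  idx <- which(matrix(TRUE, k, k) & !diag(k), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

#' Observed transition percentages
#'
#' Counts run-to-run transitions i -> j within epochs (transitions never
#' span epoch boundaries) and normalizes to percent of all transitions,
#' as an ordered-pair vector of length K(K-1).
#'
#' @param seg A smoothed `segmentation` with at least two runs.
#' @return Named numeric vector summing to 100.
#' @export
observed_transitions <- function(seg) {
  k <- seg$n_maps
  counts <- matrix(0, k, k)
  for (e in seq_along(seg$labels)) {
    v <- rle(seg$labels[[e]])$values
    if (length(v) < 2L) next
    from <- v[-length(v)]; to <- v[-1L]
    for (i in seq_along(from)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  }
  if (sum(counts) < 1) stop("segmentation has fewer than two runs")
  idx <- .pair_index(k)
  out <- 100 * counts[idx] / sum(counts)
  names(out) <- transition_pair_names(seg$map_labels)
  out
}

#' Occurrence-predicted ("expected") transition percentages
#'
#' Under random syntax, transitions are proportional to the occurrence of
#' the classes: expected(i -> j) = p_i p_j / sum over ordered distinct
#' pairs of p_k p_m, in percent.  A map with zero occurrence contributes
#' zero to all its pairs.  A row-conditional variant
#' (expected(i -> j) proportional to p_i p_j / (1 - p_i)) is available for
#' sensitivity analysis.
#'
#' @param p Per-map relative occurrence frequencies (nonnegative,
#'   normalized internally).
#' @param map_labels Optional map names for the output.
#' @param rule `"product"` (default) or `"row-conditional"`.
#' @return Named numeric vector of length K(K-1) summing to 100.
#' @export
expected_transitions <- function(p, map_labels = NULL,
                                 rule = c("product", "row-conditional")) {
  rule <- match.arg(rule)
  if (any(p < 0)) stop("occurrence frequencies must be nonnegative")
  if (sum(p) <= 0) stop("at least one map must occur")
  p <- p / sum(p)
  k <- length(p)
  idx <- .pair_index(k)
  w <- switch(rule,
    "product" = p[idx[, 1L]] * p[idx[, 2L]],
    "row-conditional" = {
      denom <- 1 - p[idx[, 1L]]
      out <- p[idx[, 1L]] * p[idx[, 2L]] / ifelse(denom > 0, denom, 1)
      out[denom <= 0] <- 0
      out
    })
  out <- 100 * w / sum(w)
  if (is.null(map_labels)) map_labels <- as.character(seq_len(k))
  names(out) <- transition_pair_names(map_labels)
  out
}

#' Chi-square distance between transition vectors
#'
#' Sum over entries of (observed - expected)^2 / expected; entries with
#' zero expected value are skipped.
#'
#' @param observed,expected Numeric vectors of equal length.
#' @return Nonnegative scalar.
#' @export
chi_square_distance <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop("observed and expected must have equal length")
  keep <- expected > 0
  if (!any(keep)) stop("all expected entries are zero")
  sum((observed[keep] - expected[keep])^2 / expected[keep])
}

#' Per-subject transition profile
#'
#' Convenience wrapper computing the observed transition percentages, the
#' occurrence-predicted expected percentages (occurrence measured as the
#' relative run count per map), and their chi-square distance.
#'
#' @param seg A smoothed `segmentation`.
#' @param rule Expected-transition rule, see [expected_transitions()].
#' @return List with `observed`, `expected`, `chi2`.
#' @export
transition_profile <- function(seg, rule = "product") {
  obs <- observed_transitions(seg)
  runs <- numeric(seg$n_maps)
  for (e in seg$labels) {
    v <- rle(e)$values
    runs <- runs + tabulate(v, seg$n_maps)
  }
  exp <- expected_transitions(runs / sum(runs), seg$map_labels, rule = rule)
  list(observed = obs, expected = exp,
       chi2 = chi_square_distance(obs, exp))
}

#' Permutation test of microstate syntax
#'
#' Tests whether the across-subject mean observed transition vector differs
#' from the mean occurrence-predicted vector.  The statistic is the
#' chi-square distance between the two group-mean 12-vectors; the null
#' distribution is built by independently swapping each subject's
#' observed/expected pair with probability 1/2 per permutation.  The
#' p-value uses the permutation-inclusive add-one convention.
#'
#' @param observed n x 12 matrix of per-subject observed percentages.
#' @param expected n x 12 matrix of per-subject expected percentages.
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed.
#' @return List with `statistic`, `p_value`, `null` (the permuted
#'   statistics).
#' @export
syntax_permutation_test <- function(observed, expected, n_perm = 5000,
                                    seed = NULL) {
  observed <- as.matrix(observed); expected <- as.matrix(expected)
  if (!all(dim(observed) == dim(expected)))
    stop("observed and expected matrices must have equal dimensions")
  n <- nrow(observed)
  if (n < 2L) stop("at least two subjects are required")
  if (n_perm < 100L) warning("fewer than 100 permutations")
  stat <- chi_square_distance(colMeans(observed), colMeans(expected))
  null <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      flip <- stats::runif(n) < 0.5
      o <- observed; e <- expected
      o[flip, ] <- expected[flip, ]
      e[flip, ] <- observed[flip, ]
      chi_square_distance(colMeans(o), colMeans(e))
    }, numeric(1))
  })
  list(statistic = stat,
       p_value = (1 + sum(null >= stat)) / (1 + n_perm),
       null = null, n_perm = n_perm)
}
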