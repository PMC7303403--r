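#' Standard 19-channel 10-20 montage
#'
#' Channel labels of the international 10-20 system in the fixed order used
#' throughout the package: Fp1, Fp2, F7, F3, Fz, F4, F8, T3, T5, T4, T6,
#' C3, Cz, C4, P3, Pz, P4, O1, O2.
#'
#' @return Character vector of 19 channel labels.
#' @export
montage_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "T5", "T4", "T6",
    "C3", "Cz", "C4", "P3", "Pz", "P4", "O1", "O2")
}

# Approximate 2-D scalp-projection coordinates of the 10-20 electrodes
# (x: left -> right, y: posterior -> anterior, unit head radius).  The layout
# is exactly mirror-symmetric about x = 0, which the template construction
# relies on.
.montage_coords <- function() {
  m <- rbind(
    Fp1 = c(-0.309,  0.951), Fp2 = c( 0.309,  0.951),
    F7  = c(-0.809,  0.588), F3  = c(-0.500,  0.500),
    Fz  = c( 0.000,  0.500), F4  = c( 0.500,  0.500),
    F8  = c( 0.809,  0.588),
    T3  = c(-1.000,  0.000), T5  = c(-0.809, -0.588),
    T4  = c( 1.000,  0.000), T6  = c( 0.809, -0.588),
    C3  = c(-0.500,  0.000), Cz  = c( 0.000,  0.000),
    C4  = c( 0.500,  0.000),
    P3  = c(-0.500, -0.500), Pz  = c( 0.000, -0.500),
    P4  = c( 0.500, -0.500),
    O1  = c(-0.309, -0.951), O2  = c( 0.309, -0.951))
  colnames(m) <- c("x", "y")
  m
}

# Left-right mirror permutation of the montage: each channel is mapped to its
# homologue across the midline (midline channels map to themselves).
.mirror_permutation <- function(montage) {
  pairs <- c(Fp1 = "Fp2", Fp2 = "Fp1", F7 = "F8", F8 = "F7", F3 = "F4",
             F4 = "F3", T3 = "T4", T4 = "T3", T5 = "T6", T6 = "T5",
             C3 = "C4", C4 = "C3", P3 = "P4", P4 = "P3", O1 = "O2",
             O2 = "O1", Fz = "Fz", Cz = "Cz", Pz = "Pz")
  match(unname(pairs[montage]), montage)
}

.avg_ref_unit <- function(v) {
  v <- v - mean(v)
  v / sqrt(sum(v^2))
}

#' Canonical microstate template maps
#'
#' Constructs synthetic stand-ins for the four archetypal resting-state
#' microstate topographies reported across the literature: A (right-frontal
#' to left-posterior diagonal gradient), B (the left-right mirror image of
#' A), C (antero-posterior gradient) and D (fronto-central focal map).
#' Each map is average-referenced (zero mean over channels) and scaled to
#' unit L2 norm; map B is generated from map A by the exact mirror channel
#' permutation, so the pair is symmetric by construction.
#'
#' @param montage Character vector of 19 channel labels from the 10-20
#'   system in the order of [montage_1020()].
#' @return An object of class `template_maps`: a list with `maps` (4 x 19
#'   numeric matrix, rows `A`, `B`, `C`, `D`), `montage`, and `labels`.
#' @examples
#' tm <- make_canonical_maps()
#' rowSums(tm$maps)            # ~0: average reference
#' sqrt(rowSums(tm$maps^2))    # 1: unit norm
#' @export
make_canonical_maps <- function(montage = montage_1020()) {
  known <- montage_1020()
  idx <- match(toupper(montage), toupper(known))
  if (anyNA(idx)) {
    stop("unknown channel label(s) in montage: ",
         paste(montage[is.na(idx)], collapse = ", "))
  }
  if (length(montage) != 19L || anyDuplicated(idx)) {
    stop("montage must contain each of the 19 ten-twenty channels exactly once")
  }
  xy <- .montage_coords()[idx, , drop = FALSE]
  x <- xy[, "x"]; y <- xy[, "y"]

  # A: lateralized diagonal pattern (right-frontal vs left-temporal) with a
  # symmetric lateral-curvature component, so that A and B stay well
  # separated from C and D and A+B is not collinear with either
  map_a <- .avg_ref_unit(x * (1 + 0.4 * y) + 0.3 * y + 1.4 * x^2)
  # B: exact mirror image of A under the left-right channel swap
  map_b <- map_a[.mirror_permutation(known[idx])]
  # C: antero-posterior gradient
  map_c <- .avg_ref_unit(y)
  # D: fronto-central focal topography
  map_d <- .avg_ref_unit(exp(-((x - 0)^2 + (y - 0.35)^2) / (2 * 0.45^2)))

  maps <- rbind(A = map_a, B = map_b, C = map_c, D = map_d)
  colnames(maps) <- known[idx]
  structure(list(maps = maps, montage = known[idx],
                 labels = c("A", "B", "C", "D")),
            class = "template_maps")
}

#' Spatial correlation between two topographies
#'
#' Pearson correlation across channels of two scalp maps.  For
#' average-referenced maps this is the standard topographic similarity
#' measure; its absolute value is what polarity-invariant comparisons use.
#'
#' @param a,b Numeric channel vectors of equal length.
#' @return Scalar correlation in \[-1, 1\].
#' @export
spatial_correlation <- function(a, b) {
  stats::cor(as.numeric(a), as.numeric(b))
}

#' @export
print.template_maps <- function(x, ...) {
  cat("Template maps:", nrow(x$maps), "maps x", ncol(x$maps), "channels (",
      paste(x$labels, collapse = ", "), ")\n")
  invisible(x)
}
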