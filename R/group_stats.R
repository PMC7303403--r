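# Group-level statistics: log transform, covariate-adjusted ANCOVA,
# Benjamini-Hochberg FDR over the 24-feature battery, post hoc pairwise
# GLM contrasts, and partial correlation.

#' Log-transform feature columns
#'
#' Applies the natural log to positive-valued feature columns.  Zeros
#' (possible for transition percentages in short recordings) are offset by
#' half the smallest positive value observed in that column; affected
#' columns are flagged in the `"zero_offset"` attribute.  Negative values
#' are an error.
#'
#' @param table Data frame.
#' @param feature_cols Character vector of columns to transform.
#' @return The data frame with transformed columns.
#' @export
log_features <- function(table, feature_cols) {
  flagged <- character(0)
  for (cn in feature_cols) {
    v <- table[[cn]]
    if (any(v < 0, na.rm = TRUE))
      stop("negative values in feature ", cn, " cannot be log-transformed")
    zero <- !is.na(v) & v == 0
    if (any(zero)) {
      pos <- v[!is.na(v) & v > 0]
      if (length(pos) == 0L)
        stop("feature ", cn, " is identically zero")
      v[zero] <- min(pos) / 2
      flagged <- c(flagged, cn)
    }
    table[[cn]] <- log(v)
  }
  attr(table, "zero_offset") <- flagged
  table
}

.prep_covariates <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n) stop("covariate rows must match subjects")
  keep <- vapply(covariates, function(v) {
    v <- v[!is.na(v)]
    length(unique(v)) > 1L
  }, logical(1))
  if (!all(keep)) covariates <- covariates[, keep, drop = FALSE]
  if (ncol(covariates) == 0L) return(NULL)
  covariates
}

#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Fits the linear model `feature ~ covariates + group` and tests the group
#' factor by the Type II F-test (the increment of the group factor over the
#' covariate-only model).  Zero-variance covariate columns are dropped,
#' reducing to a one-way ANOVA when none remain.  Complete cases only.
#'
#' @param feature Numeric per-subject response.
#' @param group Factor (or coercible) of group membership.
#' @param covariates Optional data frame / matrix of covariates.
#' @return List with `F`, `df` (c(numerator, denominator)), `p`, `n`.
#' @export
ancova <- function(feature, group, covariates = NULL) {
  group <- droplevels(as.factor(group))
  n <- length(feature)
  covariates <- .prep_covariates(covariates, n)
  df <- data.frame(.y = feature, .group = group)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) <= nlevels(group) + if (is.null(covariates)) 0 else ncol(covariates))
    stop("too few complete cases for the model")
  rhs <- if (is.null(covariates)) "1" else
    paste(sprintf("`%s`", colnames(covariates)), collapse = " + ")
  reduced <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = df)
  full <- stats::lm(stats::as.formula(paste(".y ~", rhs, "+ .group")),
                    data = df)
  cf <- stats::coef(full)
  bad <- names(cf)[is.na(cf)]
  bad <- setdiff(bad, grep("^\\.group", names(cf), value = TRUE))
  if (length(bad))
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  a <- stats::anova(reduced, full)
  list(F = a$F[2L], df = c(a$Df[2L], a$Res.Df[2L]), p = a$`Pr(>F)`[2L],
       n = nrow(df))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate over a
#' battery of `m` comparisons (monotonicity enforced); `m` may exceed the
#' number of p-values supplied.
#'
#' @param pvalues Numeric vector of raw p-values in \[0, 1\].
#' @param m Battery size (default: number of p-values).
#' @return Adjusted p-values.
#' @export
fdr_bh <- function(pvalues, m = length(pvalues)) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (m < length(pvalues)) stop("m must be at least the number of p-values")
  stats::p.adjust(pvalues, method = "BH", n = m)
}

#' Pairwise post hoc contrast (GLM with covariates)
#'
#' Restricted to two groups, fits `feature ~ covariates + group` and
#' returns the t-test of the group coefficient (uncorrected).  Intended to
#' be run only when the omnibus test survives FDR correction.
#'
#' @param feature Numeric response.
#' @param group Group factor.
#' @param pair Length-2 character vector naming the two groups.
#' @param covariates Optional covariates.
#' @return List with `t`, `df`, `p`, `pair`.
#' @export
posthoc_pair <- function(feature, group, pair, covariates = NULL) {
  group <- as.character(group)
  sel <- group %in% pair
  g <- factor(group[sel], levels = pair)
  if (any(table(g) < 3L)) stop("each group in the pair needs >= 3 subjects")
  covs <- if (is.null(covariates)) NULL else
    as.data.frame(covariates)[sel, , drop = FALSE]
  covs <- .prep_covariates(covs, sum(sel))
  df <- data.frame(.y = feature[sel], .group = g)
  if (!is.null(covs)) df <- cbind(df, covs)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  rhs <- if (is.null(covs)) ".group" else
    paste(paste(sprintf("`%s`", colnames(covs)), collapse = " + "), "+ .group")
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = df)
  sm <- stats::summary.lm(fit)$coefficients
  row <- grep("^\\.group", rownames(sm))
  list(t = sm[row, "t value"], df = fit$df.residual,
       p = sm[row, "Pr(>|t|)"], pair = pair)
}

#' Partial correlation
#'
#' Correlation of the residuals of `x` and `y` after regressing each on the
#' covariates; the p-value comes from the t-distribution with
#' n - 2 - q degrees of freedom (q covariates).  Complete cases only.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional covariates.
#' @return List with `rho`, `df`, `p`, `n`; `rho` is `NA` (with a message)
#'   if either residual variance is zero.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n0 <- length(x)
  covariates <- .prep_covariates(covariates, n0)
  df <- data.frame(.x = x, .y = y)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  q <- if (is.null(covariates)) 0L else ncol(covariates)
  n <- nrow(df)
  if (n <= q + 2L) stop("too few complete cases")
  if (q == 0L) {
    rx <- df$.x - mean(df$.x); ry <- df$.y - mean(df$.y)
  } else {
    rhs <- paste(sprintf("`%s`", colnames(covariates)), collapse = " + ")
    rx <- stats::resid(stats::lm(stats::as.formula(paste(".x ~", rhs)), df))
    ry <- stats::resid(stats::lm(stats::as.formula(paste(".y ~", rhs)), df))
  }
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    message("zero residual variance; partial correlation undefined")
    return(list(rho = NA_real_, df = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  dfree <- n - 2L - q
  tval <- rho * sqrt(dfree / (1 - rho^2))
  list(rho = rho, df = dfree, p = 2 * stats::pt(-abs(tval), dfree), n = n)
}

#' Run the ANCOVA + FDR battery over a feature set
#'
#' Applies the log transform, runs the covariate-adjusted ANCOVA per
#' feature, adjusts the battery with Benjamini-Hochberg FDR (battery size
#' `m`, asserted against the number of features), and computes pairwise
#' post hoc contrasts only for features significant after FDR.
#'
#' @param table Data frame with one row per subject.
#' @param feature_cols Feature column names (the battery).
#' @param group_col Name of the group column.
#' @param covariate_cols Covariate column names (may be empty).
#' @param m Battery size for FDR (default: number of features).
#' @param alpha Significance level gating post hoc tests (default 0.05).
#' @param log_transform Apply [log_features()] first (default TRUE).
#' @return Data frame, one row per feature: `feature`, `F`, `df1`, `df2`,
#'   `p`, `p_fdr`, `significant`, plus post hoc `t_<A>_vs_<B>` /
#'   `p_<A>_vs_<B>` columns (NA where the omnibus was not significant).
#' @export
run_group_battery <- function(table, feature_cols, group_col = "group",
                              covariate_cols = character(0),
                              m = length(feature_cols), alpha = 0.05,
                              log_transform = TRUE) {
  stopifnot(length(feature_cols) == m)
  if (log_transform) table <- log_features(table, feature_cols)
  covs <- if (length(covariate_cols))
    table[, covariate_cols, drop = FALSE] else NULL
  group <- droplevels(as.factor(table[[group_col]]))
  res <- lapply(feature_cols, function(cn)
    ancova(table[[cn]], group, covs))
  p <- vapply(res, `[[`, numeric(1), "p")
  p_fdr <- fdr_bh(p, m = m)
  out <- data.frame(feature = feature_cols,
                    F = vapply(res, `[[`, numeric(1), "F"),
                    df1 = vapply(res, function(r) r$df[1], numeric(1)),
                    df2 = vapply(res, function(r) r$df[2], numeric(1)),
                    p = p, p_fdr = p_fdr,
                    significant = p_fdr < alpha,
                    stringsAsFactors = FALSE)
  pairs <- utils::combn(levels(group), 2L, simplify = FALSE)
  for (pr in pairs) {
    tc <- sprintf("t_%s_vs_%s", pr[1], pr[2])
    pc <- sprintf("p_%s_vs_%s", pr[1], pr[2])
    out[[tc]] <- NA_real_; out[[pc]] <- NA_real_
    for (i in which(out$significant)) {
      ph <- posthoc_pair(table[[feature_cols[i]]], group, pr, covs)
      out[[tc]][i] <- ph$t; out[[pc]][i] <- ph$p
    }
  }
  out
}
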