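# Feature compression and leave-one-out cross-validated classification.

.zscore_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(mu = mu, sd = sd)
}
.zscore_apply <- function(x, z) {
  sweep(sweep(x, 2L, z$mu), 2L, z$sd, "/")
}

#' Assemble the per-subject feature matrix
#'
#' Binds per-band feature blocks (each a subjects x 24 matrix: duration,
#' occurrence and coverage for each of the four maps plus the 12 transition
#' percentages) into one matrix and z-scores every column.  `"broadband"`
#' selects the broadband block alone (24 columns); `"all"` selects
#' broadband plus the four frequency bands (120 columns).  Columns are
#' tagged with their band in the `"band"` attribute.
#'
#' @param band_features Named list of subjects x 24 numeric matrices.
#' @param bands `"broadband"` or `"all"`.
#' @return Z-scored numeric matrix with attribute `"band"`.
#' @export
build_feature_matrix <- function(band_features, bands = c("broadband", "all")) {
  bands <- match.arg(bands)
  want <- if (bands == "broadband") "broadband" else
    c("broadband", "delta", "theta", "alpha", "beta")
  missing <- setdiff(want, names(band_features))
  if (length(missing))
    stop("missing feature blocks for band(s): ",
         paste(missing, collapse = ", "))
  blocks <- lapply(want, function(b) {
    m <- as.matrix(band_features[[b]])
    if (anyNA(m)) {
      bad <- which(rowSums(is.na(m)) > 0)
      stop("missing features in band ", b, " for subject row(s): ",
           paste(bad, collapse = ", "))
    }
    colnames(m) <- paste(b, colnames(m), sep = ".")
    m
  })
  x <- do.call(cbind, blocks)
  z <- .zscore_fit(x)
  out <- .zscore_apply(x, z)
  attr(out, "band") <- rep(want, vapply(blocks, ncol, integer(1)))
  out
}

#' Principal-component compression
#'
#' Retains the smallest number of leading principal components whose
#' cumulative explained variance reaches `retained_variance`.
#'
#' @param x Numeric matrix (subjects x features).
#' @param retained_variance Fraction of variance to retain (default 0.99).
#' @return List with `scores`, `rotation`, `center`, `n_components`,
#'   `explained` (cumulative variance fractions).
#' @export
pca_compress <- function(x, retained_variance = 0.99) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("at least two subjects are required")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  if (sum(v) == 0) stop("constant matrix has no principal components")
  cumv <- cumsum(v) / sum(v)
  nc <- which(cumv >= retained_variance - 1e-12)[1L]
  list(scores = pc$x[, seq_len(nc), drop = FALSE],
       rotation = pc$rotation[, seq_len(nc), drop = FALSE],
       center = pc$center, n_components = nc, explained = cumv)
}

.fit_predict <- function(model, xtr, ytr, xte, seed) {
  dtr <- data.frame(.y = ytr, xtr, check.names = FALSE)
  dte <- data.frame(xte, check.names = FALSE)
  switch(model,
    multinomial = ,
    logistic = {
      if (model == "logistic" && nlevels(ytr) != 2L)
        stop("logistic regression requires exactly two classes")
      fit <- nnet::multinom(.y ~ ., data = dtr, trace = FALSE,
                            decay = 1e-6, maxit = 500)
      as.character(stats::predict(fit, newdata = dte))
    },
    lda = {
      fit <- MASS::lda(xtr, grouping = ytr)
      as.character(stats::predict(fit, newdata = xte)$class)
    },
    qda = {
      fit <- MASS::qda(xtr, grouping = ytr)
      as.character(stats::predict(fit, newdata = xte)$class)
    },
    svm = {
      # RBF kernel with a small inner cross-validated grid over (C, gamma)
      tn <- e1071::tune.svm(
        xtr, ytr, kernel = "radial", scale = FALSE,
        cost = c(1, 10, 100), gamma = c(0.1, 1, 10) / ncol(xtr),
        tunecontrol = e1071::tune.control(sampling = "cross", cross = 5))
      as.character(stats::predict(tn$best.model, newdata = xte))
    },
    stop("unknown model: ", model))
}

#' Leave-one-out cross-validated classification
#'
#' For every subject, fits the preprocessing (z-scoring and, optionally,
#' PCA retaining 99% of variance) and the classifier on the remaining
#' subjects and predicts the held-out subject.  By default preprocessing is
#' fold-internal (no leakage); `paper_mode = TRUE` computes z-scores and
#' PCA once on the full matrix before cross-validation, for comparison
#' with analyses that do not refit per fold.  By convention PCA is applied
#' for multinomial/logistic/QDA and skipped for LDA and SVM.
#'
#' @param x Subjects x features numeric matrix (raw; z-scoring is internal).
#' @param y Class labels (factor or coercible); >= 2 classes with >= 2
#'   subjects each.
#' @param model One of `"multinomial"`, `"logistic"`, `"lda"`, `"qda"`,
#'   `"svm"`.
#' @param use_pca Logical or `NULL` (model-dependent default).
#' @param retained_variance PCA variance threshold (default 0.99).
#' @param paper_mode Compute preprocessing once on the full matrix
#'   (default FALSE).
#' @param control_class Class treated as the control for specificity
#'   (default `"HC"` when present, else the first level).
#' @param seed Integer seed (affects only the SVM's inner
#'   cross-validation splits; the other models are deterministic).
#' @return A `classifier_result`: `model`, `classes`, `accuracy` (percent),
#'   `sensitivity` (per-class, percent), `specificity` (percent correct in
#'   the control class), `confusion` (true x predicted), `predictions`,
#'   `n_failed_folds`.
#' @export
loo_cv <- function(x, y, model = c("multinomial", "logistic", "lda", "qda",
                                   "svm"),
                   use_pca = NULL, retained_variance = 0.99,
                   paper_mode = FALSE, control_class = NULL, seed = NULL) {
  model <- match.arg(model)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("at least two classes are required")
  if (model == "logistic" && nlevels(y) != 2L)
    stop("logistic regression requires exactly two classes")
  if (any(table(y) < 2L)) stop("every class needs at least two subjects")
  if (is.null(use_pca))
    use_pca <- model %in% c("multinomial", "logistic", "qda")
  n <- nrow(x)
  if (paper_mode) {
    z <- .zscore_fit(x)
    xall <- .zscore_apply(x, z)
    if (use_pca) {
      pc <- pca_compress(xall, retained_variance)
      xall <- pc$scores
    }
  }
  preds <- character(n)
  failed <- 0L
  .with_seed(seed, for (i in seq_len(n)) {
    if (paper_mode) {
      xtr <- xall[-i, , drop = FALSE]; xte <- xall[i, , drop = FALSE]
    } else {
      z <- .zscore_fit(x[-i, , drop = FALSE])
      xtr <- .zscore_apply(x[-i, , drop = FALSE], z)
      xte <- .zscore_apply(x[i, , drop = FALSE], z)
      if (use_pca) {
        pc <- pca_compress(xtr, retained_variance)
        xtr <- pc$scores
        xte <- sweep(xte, 2L, pc$center) %*% pc$rotation
      }
    }
    colnames(xtr) <- colnames(xte) <- paste0("V", seq_len(ncol(xtr)))
    pred <- tryCatch(.fit_predict(model, xtr, droplevels(y[-i]), xte, seed),
                     error = function(e) NA_character_)
    if (is.na(pred)) failed <- failed + 1L
    preds[i] <- pred
  })
  classes <- levels(y)
  if (is.null(control_class))
    control_class <- if ("HC" %in% classes) "HC" else classes[1L]
  correct <- !is.na(preds) & preds == as.character(y)
  confusion <- table(true = y, predicted = factor(preds, levels = classes))
  sens <- vapply(classes, function(cl)
    100 * mean(correct[y == cl]), numeric(1))
  structure(list(model = model, classes = classes,
                 accuracy = 100 * mean(correct),
                 sensitivity = sens,
                 specificity = unname(sens[control_class]),
                 confusion = confusion,
                 predictions = preds, truth = as.character(y),
                 n_failed_folds = failed),
            class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf("%s LOO-CV: accuracy %.1f%% (specificity %.1f%%)\n",
              x$model, x$accuracy, x$specificity))
  print(x$confusion)
  invisible(x)
}
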