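#' Standardized principal component analysis
#'
#' Each target is z-scored (mean 0, variance 1) so assays contribute equally,
#' then components are extracted by singular-value decomposition. Signs
#' follow a deterministic convention: within each component the
#' largest-magnitude loading is positive.
#'
#' @param dct a [delta_ct_table()] of retained cells.
#' @param target_subset target ids to include (e.g. the protein panel);
#'   default all. Zero-variance targets are excluded with a warning.
#' @return list of class `pca_result`: `scores` (cells x components),
#'   `loadings` (targets x components), `variance_fraction`, `targets`,
#'   `cells`.
#' @export
pca_standardized <- function(dct, target_subset = NULL) {
  stopifnot(inherits(dct, "DeltaCtTable"))
  cells <- cells_only(dct)
  if (is.null(target_subset)) target_subset <- cells$targets$target_id
  m <- cells$dct[, target_subset, drop = FALSE]
  if (nrow(m) < 3 || ncol(m) < 2) stop("need >= 3 cells and >= 2 targets",
                                       call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (all(sds == 0)) stop("all targets constant", call. = FALSE)
  if (any(sds == 0)) {
    warning("zero-variance target(s) excluded: ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  z <- scale(m)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  # deterministic sign: largest |loading| positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_fraction = vf, targets = colnames(m),
                 cells = cells$wells$well_id,
                 time_point_hr = cells$wells$time_point_hr),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("standardized PCA:", length(x$cells), "cells x", length(x$targets),
      "targets\n")
  k <- min(5, length(x$variance_fraction))
  cat("  variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction[seq_len(k)]), collapse = " "),
      if (length(x$variance_fraction) > k) "..." else "", "\n")
  invisible(x)
}

#' Random-forest time-point classification on principal component scores
#'
#' Training cells are drawn with replacement to `train_fraction` of the
#' sample count; cells never drawn form the test set. A random forest is
#' fit on all PC scores and evaluated per class in a one-vs-rest ROC with
#' trapezoidal AUC.
#'
#' @param pca a [pca_standardized()] result.
#' @param labels class labels per cell (defaults to the PCA's time points).
#' @param train_fraction nominal training fraction, default 0.8.
#' @param seed RNG seed.
#' @param ntree forest size, default 500.
#' @param bootstrap draw the training set with replacement (default); with
#'   `FALSE` a deterministic stratified `train_fraction` split is used.
#' @return list of class `classifier_evaluation`: per-class `auc` (named,
#'   `NA` when the class is absent from the test set), `roc` (list of
#'   data.frames with `fpr`, `tpr`), `train_ids`, `test_ids`, `seed`.
#' @export
rf_timepoint_classifier <- function(pca, labels = NULL, train_fraction = 0.8,
                                    seed = 1L, ntree = 500,
                                    bootstrap = TRUE) {
  stopifnot(inherits(pca, "pca_result"))
  if (is.null(labels)) labels <- pca$time_point_hr
  labels <- factor(labels)
  n <- nrow(pca$scores)
  stopifnot(length(labels) == n, nlevels(labels) >= 2)
  set.seed(seed)
  if (bootstrap) {
    tr <- sample.int(n, size = ceiling(train_fraction * n), replace = TRUE)
    te <- setdiff(seq_len(n), unique(tr))
  } else {
    tr <- unlist(lapply(split(seq_len(n), labels), function(ix) {
      sample(ix, size = max(1, round(train_fraction * length(ix))))
    }), use.names = FALSE)
    te <- setdiff(seq_len(n), tr)
  }
  if (!length(te)) stop("empty test set; lower train_fraction", call. = FALSE)
  fit <- randomForest::randomForest(x = pca$scores[tr, , drop = FALSE],
                                    y = labels[tr], ntree = ntree)
  prob <- stats::predict(fit, pca$scores[te, , drop = FALSE], type = "prob")
  classes <- levels(labels)
  aucs <- stats::setNames(rep(NA_real_, length(classes)), classes)
  rocs <- stats::setNames(vector("list", length(classes)), classes)
  for (cl in classes) {
    truth <- labels[te] == cl
    if (!any(truth) || all(truth)) next  # class missing from test set
    r <- pROC::roc(response = truth, predictor = prob[, cl],
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    aucs[cl] <- as.numeric(pROC::auc(r))
    rocs[[cl]] <- data.frame(fpr = 1 - r$specificities,
                             tpr = r$sensitivities)
  }
  structure(list(auc = aucs, roc = rocs,
                 train_ids = pca$cells[unique(tr)], test_ids = pca$cells[te],
                 n_train_drawn = length(tr), n_test = length(te),
                 seed = seed),
            class = "classifier_evaluation")
}

#' @export
print.classifier_evaluation <- function(x, ...) {
  cat("one-vs-rest random-forest evaluation (test n =", x$n_test, ")\n")
  for (cl in names(x$auc)) {
    cat(sprintf("  class %s: AUC %s\n", cl, fmt_or_na(x$auc[[cl]])))
  }
  invisible(x)
}

#' Correlation of a target with principal component scores
#'
#' Spearman correlation between one target's delta-Ct vector (over the
#' PCA's cells) and each of the first `components` score vectors; the
#' target need not be part of the PCA subset.
#'
#' @param dct the [delta_ct_table()] the PCA cells came from.
#' @param target target id.
#' @param pca a [pca_standardized()] result.
#' @param components how many leading components, default 2.
#' @return named numeric vector of rho per component (`NA` with attribute
#'   `degenerate` when the target is constant).
#' @export
target_pc_correlation <- function(dct, target, pca, components = 2) {
  stopifnot(inherits(dct, "DeltaCtTable"), inherits(pca, "pca_result"))
  x <- dct$dct[match(pca$cells, dct$wells$well_id), target]
  k <- min(components, ncol(pca$scores))
  out <- stats::setNames(rep(NA_real_, k), colnames(pca$scores)[seq_len(k)])
  if (stats::sd(x) == 0) {
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  for (j in seq_len(k)) {
    out[j] <- stats::cor(x, pca$scores[, j], method = "spearman")
  }
  out
}
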