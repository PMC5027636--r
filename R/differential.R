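#' Fit a two-parameter normal model to delta-Ct values
#'
#' Maximum-likelihood mean and sd over all values, with a chi-squared
#' goodness-of-fit test on equal-probability bins (expected count >= 5,
#' degrees of freedom = bins - 1 - 2).
#'
#' @param values numeric vector of delta-Ct values, length >= 10.
#' @return list of class `expression_model_fit`: `model = "NORMAL2"`,
#'   `mu`, `sigma` (ML, i.e. divisor n), `gof_p` (`NA` when n < 20 leaves
#'   no valid binning), `degenerate` flag for zero variance.
#' @export
fit_normal_model <- function(values) {
  stopifnot(length(values) >= 10)
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))
  if (sigma == 0) {
    return(structure(list(model = "NORMAL2", pi = NA_real_, mu = mu,
                          sigma = 0, gof_p = NA_real_, n = length(values),
                          degenerate = TRUE),
                     class = "expression_model_fit"))
  }
  gof <- normal_gof(values, mu, sigma, n_fitted = 2)
  structure(list(model = "NORMAL2", pi = NA_real_, mu = mu, sigma = sigma,
                 gof_p = gof, n = length(values), degenerate = FALSE),
            class = "expression_model_fit")
}

# Chi-squared GOF against Normal(mu, sigma) with k equal-probability bins,
# k chosen so expected counts are >= 5 and df = k - 1 - n_fitted >= 1.
normal_gof <- function(values, mu, sigma, n_fitted) {
  n <- length(values)
  k <- min(20L, floor(n / 5))
  if (k < n_fitted + 2L) return(NA_real_)
  brk <- stats::qnorm(seq_len(k - 1) / k, mu, sigma)
  obs <- tabulate(findInterval(values, brk) + 1L, nbins = k)
  expd <- n / k
  stat <- sum((obs - expd)^2 / expd)
  stats::pchisq(stat, df = k - 1L - n_fitted, lower.tail = FALSE)
}

#' Fit the three-parameter (fraction expressing + normal) model
#'
#' `pi` is the detected fraction at the target's detection threshold; the
#' normal component is ML-fit on the detected values only, with the
#' chi-squared goodness-of-fit evaluated on that component.
#'
#' @param values numeric delta-Ct vector, length >= 10.
#' @param threshold detection threshold in cycles (or one-row
#'   [detection_threshold()] slice), default 0.
#' @return list of class `expression_model_fit`: `model = "MIXTURE3"`,
#'   `pi`, `mu`, `sigma` (both `NA` when fewer than 4 values are detected),
#'   `gof_p`.
#' @export
fit_three_param_model <- function(values, threshold = 0) {
  stopifnot(length(values) >= 10)
  if (is.data.frame(threshold)) threshold <- threshold$threshold_dct
  det <- values[call_detection(values, threshold)]
  pi_hat <- length(det) / length(values)
  if (length(det) < 4) {
    return(structure(list(model = "MIXTURE3", pi = pi_hat, mu = NA_real_,
                          sigma = NA_real_, gof_p = NA_real_,
                          n = length(values), degenerate = length(det) > 0),
                     class = "expression_model_fit"))
  }
  mu <- mean(det)
  sigma <- sqrt(mean((det - mu)^2))
  gof <- if (sigma > 0) normal_gof(det, mu, sigma, n_fitted = 2) else NA_real_
  structure(list(model = "MIXTURE3", pi = pi_hat, mu = mu, sigma = sigma,
                 gof_p = gof, n = length(values), degenerate = sigma == 0),
            class = "expression_model_fit")
}

#' @export
print.expression_model_fit <- function(x, ...) {
  cat(sprintf("%s fit (n=%d): pi=%s mu=%s sigma=%s gof_p=%s%s\n",
              x$model, x$n, fmt_or_na(x$pi), fmt_or_na(x$mu),
              fmt_or_na(x$sigma), fmt_or_na(x$gof_p),
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

fmt_or_na <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)

#' Fisher test for a difference in detection proportion
#'
#' Two-sided Fisher's exact test on the 2x2 detected/undetected x group
#' table, run only when the total number of undetected cells across both
#' groups exceeds `min_undetected` (else the test is marked skipped).
#'
#' @param values_a,values_b delta-Ct values of the two cell groups.
#' @param threshold detection threshold in cycles.
#' @param min_undetected eligibility floor on total undetected, default 10.
#' @return list: `test = "FISHER_DETECTION"`, `p_value` (`NA` when
#'   skipped), `skipped`, `direction` (`"UP"` when group b detects more
#'   often), `n_a`, `n_b`.
#' @export
detection_proportion_test <- function(values_a, values_b, threshold = 0,
                                      min_undetected = 10) {
  if (is.data.frame(threshold)) threshold <- threshold$threshold_dct
  da <- call_detection(values_a, threshold)
  db <- call_detection(values_b, threshold)
  n_undet <- sum(!da) + sum(!db)
  if (n_undet <= min_undetected) {
    return(list(test = "FISHER_DETECTION", p_value = NA_real_,
                skipped = TRUE, direction = NA_character_,
                n_a = length(da), n_b = length(db)))
  }
  tab <- matrix(c(sum(da), sum(!da), sum(db), sum(!db)), 2,
                dimnames = list(c("det", "undet"), c("a", "b")))
  p <- stats::fisher.test(tab)$p.value
  dir <- if (mean(db) >= mean(da)) "UP" else "DOWN"
  list(test = "FISHER_DETECTION", p_value = p, skipped = FALSE,
       direction = dir, n_a = length(da), n_b = length(db))
}

#' Mann-Whitney U test for an expression-level shift among detected cells
#'
#' Two-sided Mann-Whitney U on the detected values only, run only when the
#' total number of detected cells across both groups exceeds
#' `min_detected` (else marked skipped).
#'
#' @inheritParams detection_proportion_test
#' @param min_detected eligibility floor on total detected, default 10.
#' @param force run even when ineligible (for exact small-sample checks).
#' @return list: `test = "MWU_LEVEL"`, `p_value`, `skipped`, `direction`
#'   (from the median difference), `n_a`, `n_b` (detected counts).
#' @export
expression_shift_test <- function(values_a, values_b, threshold = 0,
                                  min_detected = 10, force = FALSE) {
  if (is.data.frame(threshold)) threshold <- threshold$threshold_dct
  xa <- values_a[call_detection(values_a, threshold)]
  xb <- values_b[call_detection(values_b, threshold)]
  if (!force && (length(xa) + length(xb) <= min_detected ||
                 length(xa) == 0 || length(xb) == 0)) {
    return(list(test = "MWU_LEVEL", p_value = NA_real_, skipped = TRUE,
                direction = NA_character_,
                n_a = length(xa), n_b = length(xb)))
  }
  p <- suppressWarnings(stats::wilcox.test(xa, xb, exact = TRUE)$p.value)
  dir <- if (stats::median(xb) >= stats::median(xa)) "UP" else "DOWN"
  list(test = "MWU_LEVEL", p_value = p, skipped = FALSE, direction = dir,
       n_a = length(xa), n_b = length(xb))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   preserved).
#' @return adjusted p-values (monotone, capped at 1).
#' @export
bh_adjust <- function(p_values) {
  # floating-point slack: exact tests can return 1 + 2e-16
  stopifnot(all(p_values >= 0 & p_values <= 1 + 1e-8, na.rm = TRUE))
  stats::p.adjust(pmin(p_values, 1), method = "BH")
}

#' Differential tests between two cell groups for a set of targets
#'
#' Runs the detection-proportion (Fisher) and expression-shift
#' (Mann-Whitney) tests for every target between two arbitrary cell groups
#' and applies one BH correction across all executed tests.
#'
#' @param dct a [delta_ct_table()].
#' @param group_a,group_b disjoint character vectors of well ids.
#' @param targets target ids to test; default all.
#' @param thresholds optional [detection_threshold()] data.frame; targets
#'   absent from it use threshold 0.
#' @param min_count eligibility floor shared by both tests, default 10.
#' @return data.frame: one row per target x test with `p_value`,
#'   `p_adjusted`, `direction`, `skipped` and group sizes.
#' @export
de_between_groups <- function(dct, group_a, group_b, targets = NULL,
                              thresholds = NULL, min_count = 10) {
  stopifnot(inherits(dct, "DeltaCtTable"))
  if (length(intersect(group_a, group_b))) {
    stop("cell groups must be disjoint", call. = FALSE)
  }
  if (is.null(targets)) targets <- dct$targets$target_id
  ia <- match(group_a, dct$wells$well_id)
  ib <- match(group_b, dct$wells$well_id)
  if (anyNA(ia) || anyNA(ib)) stop("unknown well id in groups", call. = FALSE)
  rows <- list()
  for (id in targets) {
    thr <- threshold_for(thresholds, id)
    va <- dct$dct[ia, id]; vb <- dct$dct[ib, id]
    f <- detection_proportion_test(va, vb, thr, min_undetected = min_count)
    m <- expression_shift_test(va, vb, thr, min_detected = min_count)
    for (t in list(f, m)) {
      rows[[length(rows) + 1L]] <- data.frame(
        response_target = id, test = t$test, p_value = t$p_value,
        direction = if (is.na(t$direction)) NA_character_ else t$direction,
        skipped = t$skipped, n_a = t$n_a, n_b = t$n_b,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  run <- !out$skipped
  out$p_adjusted[run] <- bh_adjust(out$p_value[run])
  out
}

threshold_for <- function(thresholds, id) {
  if (!is.null(thresholds) && id %in% thresholds$target_id) {
    thresholds$threshold_dct[thresholds$target_id == id][1]
  } else 0
}

#' In-silico gating screen over all targets
#'
#' Every target in turn becomes a gate: retained cells are bifurcated by its
#' detection, and every other target is tested for differential detection
#' (Fisher) and for an expression shift among detected cells
#' (Mann-Whitney), with BH correction applied within each gate's experiment.
#'
#' @param dct a [delta_ct_table()] of retained cells.
#' @param thresholds optional [detection_threshold()] data.frame.
#' @param gate_targets gates to use; default every target.
#' @param min_count eligibility floor for both tests, default 10.
#' @return data.frame: `gate_target` plus the columns of
#'   [de_between_groups()]; gates with an empty side are dropped with a
#'   warning.
#' @export
in_silico_gate_all <- function(dct, thresholds = NULL, gate_targets = NULL,
                               min_count = 10) {
  stopifnot(inherits(dct, "DeltaCtTable"), ncol(dct$dct) >= 2)
  cells <- cells_only(dct)
  if (is.null(gate_targets)) gate_targets <- cells$targets$target_id
  rows <- list()
  for (g in gate_targets) {
    thr <- threshold_for(thresholds, g)
    pos <- call_detection(cells$dct[, g], thr)
    if (!any(pos) || all(pos)) {
      warning("gate ", g, " has an empty side; skipped")
      next
    }
    res <- de_between_groups(
      cells, group_a = cells$wells$well_id[!pos],
      group_b = cells$wells$well_id[pos],
      targets = setdiff(cells$targets$target_id, g),
      thresholds = thresholds, min_count = min_count)
    res <- cbind(gate_target = g, res, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) stop("no gate produced two non-empty sides", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
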