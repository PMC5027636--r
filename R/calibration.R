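#' Detection threshold on the delta-Ct scale
#'
#' After normalization the background sits at delta-Ct 0, so under a
#' one-sided normal background model a value is called real at confidence
#' `alpha` when it exceeds `qnorm(1 - alpha) * bg_sd`.
#'
#' @param bg a [estimate_protein_background()] result (or any data.frame
#'   with `target_id` and `bg_sd`).
#' @param alpha one-sided tail probability, default 0.01.
#' @return data.frame per target: `target_id`, `threshold_dct`, `alpha`.
#' @export
detection_threshold <- function(bg, alpha = 0.01) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0,1)", call. = FALSE)
  z <- stats::qnorm(1 - alpha)
  data.frame(target_id = bg$target_id,
             threshold_dct = pmax(z * bg$bg_sd, 0),
             alpha = alpha, stringsAsFactors = FALSE)
}

#' Call detection of delta-Ct values against a threshold
#'
#' Detected means strictly above the threshold; a value exactly at the
#' threshold (in particular 0 against a zero threshold) is not detected.
#'
#' @param dct_value numeric vector of delta-Ct values.
#' @param threshold a single threshold in cycles, or a one-row slice of a
#'   [detection_threshold()] result.
#' @return logical vector.
#' @export
call_detection <- function(dct_value, threshold) {
  if (is.data.frame(threshold)) threshold <- threshold$threshold_dct
  stopifnot(length(threshold) == 1, threshold >= 0)
  dct_value > threshold
}

#' Build per-target replicate dilution series from a normalized table
#'
#' @param dct a [delta_ct_table()] of `DILUTION` wells (from
#'   [dilution_delta_ct()]).
#' @param target_id which assay to extract.
#' @return list of class `dilution_series`: `target_id`, `quantities`
#'   (descending), `dct` (quantities x replicates matrix).
#' @export
dilution_series <- function(dct, target_id) {
  stopifnot(inherits(dct, "DeltaCtTable"),
            target_id %in% dct$targets$target_id)
  di <- which(dct$wells$sample_type == "DILUTION")
  q <- dct$wells$dilution_quantity[di]
  v <- dct$dct[di, target_id]
  lev <- sort(unique(q), decreasing = TRUE)
  reps <- table(factor(q, levels = lev))
  if (length(lev) < 2) stop("need >= 2 dilution levels", call. = FALSE)
  if (length(unique(reps)) != 1) {
    stop("unbalanced replicate counts across dilution levels", call. = FALSE)
  }
  m <- t(vapply(lev, function(l) v[q == l], numeric(reps[1])))
  rownames(m) <- as.character(lev)
  structure(list(target_id = target_id, quantities = lev, dct = m),
            class = "dilution_series")
}

#' Select the best contiguous linear window of a dilution series
#'
#' Regresses the replicate-mean delta-Ct on log2(quantity) inside every
#' contiguous window of at least 3 levels and returns the window that
#' maximizes `R^2 - range_cost * n_removed`, where `n_removed` counts the
#' levels outside the window. Ties prefer the longer window, then the
#' earlier start. A window whose responses have zero variance scores
#' `R^2 = 0`.
#'
#' @param series a [dilution_series()].
#' @param range_cost penalty per removed level, default 0.03.
#' @param override optional `c(lo, hi)` 1-based window indices forcing the
#'   fit to that window (audited replacement for manual range editing).
#' @return list of class `linear_range_fit`: `target_id`, `lo_index`,
#'   `hi_index`, `slope` (cycles per doubling of quantity), `intercept`,
#'   `r2`, `n_removed`, `score`.
#' @export
select_linear_range <- function(series, range_cost = 0.03, override = NULL) {
  stopifnot(inherits(series, "dilution_series"))
  y_all <- rowMeans(series$dct)
  x_all <- log2(series$quantities)
  n <- length(y_all)
  if (n < 3) stop("need >= 3 dilution levels", call. = FALSE)
  window_fit <- function(lo, hi) {
    x <- x_all[lo:hi]; y <- y_all[lo:hi]
    if (stats::sd(y) == 0) {
      return(list(slope = 0, intercept = mean(y), r2 = 0))
    }
    f <- stats::lm.fit(cbind(1, x), y)
    ssr <- sum(f$residuals^2)
    sst <- sum((y - mean(y))^2)
    list(slope = f$coefficients[2], intercept = f$coefficients[1],
         r2 = 1 - ssr / sst)
  }
  if (!is.null(override)) {
    lo <- override[1]; hi <- override[2]
    stopifnot(lo >= 1, hi <= n, hi - lo + 1 >= 3)
    f <- window_fit(lo, hi)
    return(structure(list(target_id = series$target_id, lo_index = lo,
                          hi_index = hi, slope = unname(f$slope),
                          intercept = unname(f$intercept), r2 = f$r2,
                          n_removed = n - (hi - lo + 1),
                          score = f$r2 - range_cost * (n - (hi - lo + 1)),
                          override = TRUE),
                     class = "linear_range_fit"))
  }
  best <- NULL
  for (lo in 1:(n - 2)) {
    for (hi in (lo + 2):n) {
      f <- window_fit(lo, hi)
      len <- hi - lo + 1
      score <- f$r2 - range_cost * (n - len)
      if (is.null(best) || score > best$score ||
          (score == best$score && len > best$len) ||
          (score == best$score && len == best$len && lo < best$lo)) {
        best <- list(lo = lo, hi = hi, len = len, score = score, fit = f)
      }
    }
  }
  structure(list(target_id = series$target_id, lo_index = best$lo,
                 hi_index = best$hi, slope = unname(best$fit$slope),
                 intercept = unname(best$fit$intercept), r2 = best$fit$r2,
                 n_removed = n - best$len, score = best$score,
                 override = FALSE),
            class = "linear_range_fit")
}

#' @export
print.linear_range_fit <- function(x, ...) {
  cat(sprintf(
    "linear range fit [%s]: levels %d..%d, slope %.3f, R2 %.4f, score %.4f (%d removed)\n",
    x$target_id, x$lo_index, x$hi_index, x$slope, x$r2, x$score, x$n_removed))
  invisible(x)
}

#' Limit of detection of a dilution series
#'
#' The smallest quantity at which at least `min_detected` of the replicates
#' are detected at the threshold. With a replicate count different from
#' `replicates`, the rule scales proportionally
#' (`ceiling(min_detected / replicates * n)`).
#'
#' @param series a [dilution_series()].
#' @param threshold detection threshold in cycles (or one-row
#'   [detection_threshold()] slice).
#' @param min_detected,replicates the detected-replicate rule, default 7 of 8.
#' @return list: `target_id`, `lod_quantity` (`NA` when no level
#'   qualifies), `detected_counts` per level.
#' @export
limit_of_detection <- function(series, threshold, min_detected = 7,
                               replicates = 8) {
  stopifnot(inherits(series, "dilution_series"))
  if (is.data.frame(threshold)) threshold <- threshold$threshold_dct
  n_rep <- ncol(series$dct)
  need <- if (n_rep == replicates) min_detected
          else ceiling(min_detected / replicates * n_rep)
  counts <- rowSums(series$dct > threshold)
  ok <- which(counts >= need)
  lod <- if (length(ok)) min(series$quantities[ok]) else NA_real_
  list(target_id = series$target_id, lod_quantity = lod,
       detected_counts = as.integer(counts), required = as.integer(need))
}

#' Classify probe reliability from its linear-range fit
#'
#' A probe is reliable when its selected linear window spans the single-cell
#' quantity, the mean signal at the level nearest that quantity is detected,
#' the response increases with quantity, and the window is genuinely linear
#' (window R-squared at least `min_r2` — a flat saturated response fits a
#' near-zero slope of arbitrary sign with negligible R-squared, so the
#' slope sign alone cannot separate saturation from response). Failure
#' modes: `NO_SIGNAL` (no level detected), `SATURATED` (signal above
#' threshold at at least half the levels but no usable positive linear
#' response), otherwise `RANGE_EXCLUDES_SINGLE_CELL`.
#'
#' @param fit a [select_linear_range()] result for `series`.
#' @param series the [dilution_series()] the fit was computed on.
#' @param threshold detection threshold in cycles.
#' @param single_cell_equivalents the quantity one cell corresponds to,
#'   default 1.3.
#' @param min_r2 linearity floor on the selected window, default 0.8.
#' @param min_slope minimum response in cycles per doubling of quantity,
#'   default 0.2 — a fitted slope below this is indistinguishable from
#'   replicate noise and cannot support quantification.
#' @return list of class `reliability_call`: `target_id`, `reliable`,
#'   `failure_mode`.
#' @export
classify_probe_reliability <- function(fit, series, threshold,
                                       single_cell_equivalents = 1.3,
                                       min_r2 = 0.8, min_slope = 0.2) {
  stopifnot(inherits(fit, "linear_range_fit"),
            inherits(series, "dilution_series"))
  if (is.data.frame(threshold)) threshold <- threshold$threshold_dct
  means <- rowMeans(series$dct)
  detected <- means > threshold
  win <- fit$lo_index:fit$hi_index
  qwin <- range(series$quantities[win])
  spans <- single_cell_equivalents >= qwin[1] &&
    single_cell_equivalents <= qwin[2]
  nearest <- which.min(abs(log2(series$quantities) -
                           log2(single_cell_equivalents)))
  linear_up <- fit$slope >= min_slope && fit$r2 >= min_r2
  reliable <- spans && detected[nearest] && linear_up
  mode <- if (reliable) {
    "NONE"
  } else if (!any(detected)) {
    "NO_SIGNAL"
  } else if (!linear_up && mean(detected) >= 0.5) {
    "SATURATED"
  } else {
    "RANGE_EXCLUDES_SINGLE_CELL"
  }
  structure(list(target_id = series$target_id, reliable = reliable,
                 failure_mode = mode),
            class = "reliability_call")
}

#' Calibrate every assay of a dilution plate
#'
#' Convenience wrapper running [dilution_series()], [select_linear_range()],
#' [limit_of_detection()] and [classify_probe_reliability()] per target.
#'
#' @param dct normalized `DILUTION`-well table from [dilution_delta_ct()].
#' @param thresholds a [detection_threshold()] data.frame covering the
#'   targets (targets absent from it get threshold 0).
#' @param range_cost,single_cell_equivalents,min_detected,replicates see the
#'   per-step functions.
#' @param overrides optional data.frame `target_id, lo, hi` of forced windows.
#' @return data.frame per target with fit, LOD and reliability columns.
#' @export
calibrate_assays <- function(dct, thresholds = NULL, range_cost = 0.03,
                             single_cell_equivalents = 1.3,
                             min_detected = 7, replicates = 8,
                             overrides = NULL) {
  stopifnot(inherits(dct, "DeltaCtTable"))
  rows <- lapply(dct$targets$target_id, function(id) {
    thr <- 0
    if (!is.null(thresholds) && id %in% thresholds$target_id) {
      thr <- thresholds$threshold_dct[thresholds$target_id == id]
    }
    ov <- NULL
    if (!is.null(overrides) && id %in% overrides$target_id) {
      r <- overrides[overrides$target_id == id, ][1, ]
      ov <- c(r$lo, r$hi)
    }
    s <- dilution_series(dct, id)
    f <- select_linear_range(s, range_cost = range_cost, override = ov)
    lod <- limit_of_detection(s, thr, min_detected, replicates)
    rel <- classify_probe_reliability(f, s, thr, single_cell_equivalents)
    data.frame(target_id = id, lo_index = f$lo_index, hi_index = f$hi_index,
               slope = f$slope, intercept = f$intercept, r2 = f$r2,
               n_removed = f$n_removed, score = f$score,
               lod_quantity = lod$lod_quantity,
               reliable = rel$reliable, failure_mode = rel$failure_mode,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
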