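#' Estimate protein background from zero-cell wells
#'
#' For every protein target, Ct values in zero-cell wells are clipped at the
#' Ct ceiling (undetected counts as the ceiling) and the mean and sample sd
#' over all zero-cell wells are returned. Backgrounds are pooled across time
#' points; use [check_background_homogeneity()] to justify pooling.
#'
#' @param ct a [ct_table()] containing `ZERO_CELL` wells (or, with
#'   `sample_type = "LYSIS_BUFFER"`, buffer wells).
#' @param ct_ceiling Ct ceiling (cycles), default 24.
#' @param sample_type which well class carries background, default
#'   `"ZERO_CELL"`.
#' @return data.frame of class `background_model` with one row per protein
#'   target: `target_id`, `bg_mean`, `bg_sd`, `n_wells`,
#'   `pooled_across_time`.
#' @export
estimate_protein_background <- function(ct, ct_ceiling = 24,
                                        sample_type = "ZERO_CELL") {
  stopifnot(inherits(ct, "CtTable"))
  zi <- which(ct$wells$sample_type == sample_type)
  if (length(zi) < 2) {
    stop("need >= 2 ", sample_type, " wells to estimate background; ",
         "supply lysis-buffer wells via sample_type = \"LYSIS_BUFFER\" ",
         "if the run captured no zero-cell wells", call. = FALSE)
  }
  pi_t <- which(ct$targets$analyte == "PROTEIN")
  if (!length(pi_t)) stop("no protein targets in table", call. = FALSE)
  m <- ct$ct[zi, pi_t, drop = FALSE]
  m[is.na(m)] <- ct_ceiling
  m[m > ct_ceiling] <- ct_ceiling
  tp <- unique(ct$wells$time_point_hr[zi])
  out <- data.frame(
    target_id = ct$targets$target_id[pi_t],
    bg_mean = colMeans(m),
    bg_sd = apply(m, 2, stats::sd),
    n_wells = length(zi),
    pooled_across_time = TRUE,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "time_points") <- tp
  attr(out, "ct_ceiling") <- ct_ceiling
  class(out) <- c("background_model", "data.frame")
  out
}

#' Test whether zero-cell backgrounds can be pooled across time points
#'
#' Runs all pairwise two-sided two-sample t-tests of zero-cell background Ct
#' between time points for every protein target. The verdict is `"pool"`
#' when every pairwise p-value exceeds `alpha`, else `"stratify"` with the
#' failing pair reported.
#'
#' @param ct a [ct_table()] with `ZERO_CELL` wells at >= 2 time points.
#' @param alpha significance level, default 0.05.
#' @param ct_ceiling clipping ceiling applied before testing.
#' @return data.frame per protein target: `target_id`, `verdict`,
#'   `min_p`, `failing_pair` (empty string when pooling holds).
#' @export
check_background_homogeneity <- function(ct, alpha = 0.05, ct_ceiling = 24) {
  stopifnot(inherits(ct, "CtTable"))
  zi <- which(ct$wells$sample_type == "ZERO_CELL")
  tp <- ct$wells$time_point_hr[zi]
  tps <- sort(unique(tp))
  if (length(tps) < 2) {
    stop("need >= 2 time points with zero-cell wells", call. = FALSE)
  }
  pi_t <- which(ct$targets$analyte == "PROTEIN")
  res <- lapply(pi_t, function(j) {
    x <- ct$ct[zi, j]
    x[is.na(x)] <- ct_ceiling
    x[x > ct_ceiling] <- ct_ceiling
    min_p <- 1; pair <- ""
    for (a in seq_len(length(tps) - 1)) {
      for (b in seq(a + 1, length(tps))) {
        xa <- x[tp == tps[a]]; xb <- x[tp == tps[b]]
        if (length(xa) < 2 || length(xb) < 2) {
          warning(sprintf("target %s: pair %g vs %g hr skipped (< 2 wells)",
                          ct$targets$target_id[j], tps[a], tps[b]))
          next
        }
        p <- degenerate_safe_t_test(xa, xb)
        if (p < min_p) {
          min_p <- p
          pair <- sprintf("%ghr vs %ghr", tps[a], tps[b])
        }
      }
    }
    data.frame(target_id = ct$targets$target_id[j],
               verdict = if (min_p > alpha) "pool" else "stratify",
               min_p = min_p,
               failing_pair = if (min_p > alpha) "" else pair,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# Welch t-test that tolerates zero within-group variance: identical means
# give p = 1, separated means with zero pooled variance give p = 0.
degenerate_safe_t_test <- function(xa, xb) {
  if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
    return(if (mean(xa) == mean(xb)) 1 else 0)
  }
  stats::t.test(xa, xb)$p.value
}

#' Convert RNA Ct to delta-Ct
#'
#' RNA delta-Ct is `ct_ceiling - Ct`, clipped at 0; reactions that never
#' crossed threshold (sentinel) are 0 (undetected).
#'
#' @param ct a [ct_table()].
#' @param ct_ceiling Ct ceiling (cycles), default 24.
#' @return a [delta_ct_table()] restricted to RNA targets.
#' @export
rna_delta_ct <- function(ct, ct_ceiling = 24) {
  stopifnot(inherits(ct, "CtTable"))
  ri <- ct$targets$analyte == "RNA"
  if (!any(ri)) stop("no RNA targets in table", call. = FALSE)
  m <- ct$ct[, ri, drop = FALSE]
  d <- pmax(ct_ceiling - m, 0)
  d[is.na(d)] <- 0
  delta_ct_table(d, ct$wells, ct$targets[ri, , drop = FALSE])
}

#' Convert protein Ct to delta-Ct against estimated background
#'
#' Protein Ct is first clipped at the ceiling (undetected counts as the
#' ceiling), then delta-Ct is the target's background mean minus Ct,
#' clipped at 0.
#'
#' @param ct a [ct_table()].
#' @param bg a [estimate_protein_background()] result covering every protein
#'   target in `ct`.
#' @param ct_ceiling Ct ceiling (cycles), default 24.
#' @return a [delta_ct_table()] restricted to protein targets.
#' @export
protein_delta_ct <- function(ct, bg, ct_ceiling = 24) {
  stopifnot(inherits(ct, "CtTable"))
  pi_t <- which(ct$targets$analyte == "PROTEIN")
  if (!length(pi_t)) stop("no protein targets in table", call. = FALSE)
  ids <- ct$targets$target_id[pi_t]
  miss <- setdiff(ids, bg$target_id)
  if (length(miss)) {
    stop("background missing for protein target(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  m <- ct$ct[, pi_t, drop = FALSE]
  m[is.na(m)] <- ct_ceiling
  m[m > ct_ceiling] <- ct_ceiling
  means <- bg$bg_mean[match(ids, bg$target_id)]
  d <- pmax(sweep(-m, 2, means, `+`), 0)
  delta_ct_table(d, ct$wells, ct$targets[pi_t, , drop = FALSE])
}

#' Convert dilution-series Ct to delta-Ct against lysis buffer
#'
#' Per target, the reference is the mean lysis-buffer Ct when the target was
#' detected in buffer, else the Ct ceiling; delta-Ct is `reference - Ct`
#' clipped at 0, with undetected wells 0.
#'
#' @param ct a [ct_table()] containing `DILUTION` and `LYSIS_BUFFER` wells.
#' @param ct_ceiling Ct ceiling (cycles), default 24.
#' @return a [delta_ct_table()] over the `DILUTION` wells (all targets).
#' @export
dilution_delta_ct <- function(ct, ct_ceiling = 24) {
  stopifnot(inherits(ct, "CtTable"))
  bi <- which(ct$wells$sample_type == "LYSIS_BUFFER")
  if (!length(bi)) stop("no lysis-buffer wells in table", call. = FALSE)
  di <- which(ct$wells$sample_type == "DILUTION")
  if (!length(di)) stop("no dilution wells in table", call. = FALSE)
  refs <- vapply(seq_len(ncol(ct$ct)), function(j) {
    b <- ct$ct[bi, j]
    if (all(is.na(b))) ct_ceiling else mean(b, na.rm = TRUE)
  }, numeric(1))
  m <- ct$ct[di, , drop = FALSE]
  d <- pmax(sweep(-m, 2, refs, `+`), 0)
  d[is.na(d)] <- 0
  delta_ct_table(d, ct$wells[di, , drop = FALSE], ct$targets)
}

#' Cull cells with too few detected RNAs
#'
#' A cell is retained when at least `min_detected` of the reliable RNA
#' targets are detected (delta-Ct > 0) in it; cells below the floor are
#' culled. Only `CELL` wells are subject to culling.
#'
#' @param dct a [delta_ct_table()] containing the RNA targets.
#' @param reliable_rna character vector of reliable RNA target ids to count
#'   over (must be non-empty and present in `dct`).
#' @param min_detected culling floor, default 35.
#' @return list with `dct` (the table with culled cells removed) and
#'   `qc` (data.frame per cell: `well_id`, `time_point_hr`,
#'   `n_rna_detected`, `culled`; attributes `median_before`,
#'   `median_after` hold the study medians of detected RNAs).
#' @export
cull_cells <- function(dct, reliable_rna, min_detected = 35) {
  stopifnot(inherits(dct, "DeltaCtTable"))
  if (!length(reliable_rna)) stop("reliable_rna must be non-empty", call. = FALSE)
  miss <- setdiff(reliable_rna, dct$targets$target_id)
  if (length(miss)) {
    stop("reliable RNA target(s) absent from table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ci <- which(dct$wells$sample_type == "CELL")
  counts <- rowSums(dct$dct[ci, reliable_rna, drop = FALSE] > 0)
  culled <- counts < min_detected
  if (all(culled)) {
    stop("all cells culled; detected-RNA quartiles: ",
         paste(stats::quantile(counts), collapse = ", "), call. = FALSE)
  }
  qc <- data.frame(well_id = dct$wells$well_id[ci],
                   time_point_hr = dct$wells$time_point_hr[ci],
                   n_rna_detected = as.integer(counts),
                   culled = culled, stringsAsFactors = FALSE)
  attr(qc, "median_before") <- stats::median(counts)
  attr(qc, "median_after") <- stats::median(counts[!culled])
  keep <- rep(TRUE, nrow(dct$wells))
  keep[ci[culled]] <- FALSE
  list(dct = subset_table(dct, wells = keep), qc = qc)
}
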