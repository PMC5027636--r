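#' Spearman rank correlation with average ranks
#'
#' Thin wrapper over [stats::cor()] that treats constant margins explicitly:
#' a constant vector has no rank ordering, so the coefficient is returned as
#' `NA` with a `degenerate` attribute instead of a warning-laden `NA`.
#' Zeros (undetected) participate as ordinary tied values.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Spearman rho, or `NA` (attribute `degenerate = TRUE`) when either
#'   margin is constant.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  stats::cor(x, y, method = "spearman")
}

#' Paired RNA-protein correlations per gene per time point
#'
#' For every gene measured as both RNA and protein, the Spearman correlation
#' between the two delta-Ct vectors over the retained cells of each time
#' point. Undetected zeros are included as values; set
#' `detected_only = TRUE` to restrict to cells where both analytes are
#' detected (sensitivity analysis).
#'
#' @param dct a [delta_ct_table()] of retained cells containing both
#'   analytes.
#' @param genes genes to evaluate; defaults to all genes having one RNA and
#'   one protein target in the table.
#' @param detected_only drop cells where either analyte is 0.
#' @return data.frame: `gene`, `time_point_hr`, `rho`, `n_cells`.
#' @export
paired_correlations <- function(dct, genes = NULL, detected_only = FALSE) {
  stopifnot(inherits(dct, "DeltaCtTable"))
  pairs <- paired_targets(dct, genes)
  tps <- sort(unique(dct$wells$time_point_hr[dct$wells$sample_type == "CELL"]))
  rows <- list()
  for (g in seq_len(nrow(pairs))) {
    for (tp in tps) {
      sub <- cells_only(dct, tp)
      x <- sub$dct[, pairs$rna[g]]
      y <- sub$dct[, pairs$protein[g]]
      if (detected_only) {
        keep <- x > 0 & y > 0
        x <- x[keep]; y <- y[keep]
      }
      if (length(x) < 3) next
      rho <- spearman_rho(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = pairs$gene[g], time_point_hr = tp,
        rho = as.numeric(rho), n_cells = length(x),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

paired_targets <- function(dct, genes = NULL) {
  tg <- dct$targets
  if (is.null(genes)) genes <- unique(tg$gene)
  rows <- lapply(genes, function(g) {
    r <- tg$target_id[tg$gene == g & tg$analyte == "RNA"]
    p <- tg$target_id[tg$gene == g & tg$analyte == "PROTEIN"]
    if (length(r) != 1 || length(p) != 1) {
      warning("gene ", g, " lacks a unique RNA/protein pair; skipped")
      return(NULL)
    }
    data.frame(gene = g, rna = r, protein = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stop("no complete RNA/protein pairs",
                                       call. = FALSE)
  out
}

#' Permutation test for a change in RNA-protein correlation
#'
#' The observed statistic is `rho(time_b) - rho(time_a)` for one gene. The
#' null is built by mixing the time-point labels of the pooled cells
#' `n_permutations` times (group sizes preserved) and recomputing the
#' difference; the p-value is the two-sided normal tail of the observed
#' difference under `Normal(null_mean, null_sd)`.
#'
#' @param dct a [delta_ct_table()] of retained cells.
#' @param gene gene with both analytes.
#' @param time_a,time_b the two time points (hours).
#' @param n_permutations label mixes, default 10000.
#' @param seed RNG seed recorded in the result.
#' @return data.frame: `gene`, `time_a`, `time_b`, `delta_rho`,
#'   `null_mean`, `null_sd`, `p_value`, `n_permutations`, `degenerate`.
#' @export
delta_correlation_test <- function(dct, gene, time_a, time_b,
                                   n_permutations = 10000, seed = 1L) {
  stopifnot(inherits(dct, "DeltaCtTable"))
  pr <- paired_targets(dct, gene)
  a <- cells_only(dct, time_a); b <- cells_only(dct, time_b)
  na <- nrow(a$dct); nb <- nrow(b$dct)
  if (na < 3 || nb < 3) stop("need >= 3 cells per time point", call. = FALSE)
  x <- c(a$dct[, pr$rna], b$dct[, pr$rna])
  y <- c(a$dct[, pr$protein], b$dct[, pr$protein])
  obs <- spearman_delta(x, y, seq_len(na), na + seq_len(nb))
  set.seed(seed)
  null <- vapply(seq_len(n_permutations), function(i) {
    idx <- sample.int(na + nb)
    spearman_delta(x, y, idx[seq_len(na)], idx[na + seq_len(nb)])
  }, numeric(1))
  null_mean <- mean(null, na.rm = TRUE)
  null_sd <- stats::sd(null, na.rm = TRUE)
  if (is.na(null_sd) || null_sd == 0) {
    p <- if (isTRUE(all.equal(obs, null_mean))) 1 else 0
    degen <- TRUE
  } else {
    p <- 2 * stats::pnorm(-abs(obs - null_mean) / null_sd)
    degen <- FALSE
  }
  data.frame(gene = gene, time_a = time_a, time_b = time_b,
             delta_rho = obs, null_mean = null_mean, null_sd = null_sd,
             p_value = p, n_permutations = n_permutations,
             degenerate = degen, stringsAsFactors = FALSE)
}

spearman_delta <- function(x, y, ia, ib) {
  ra <- suppressWarnings(stats::cor(x[ia], y[ia], method = "spearman"))
  rb <- suppressWarnings(stats::cor(x[ib], y[ib], method = "spearman"))
  rb - ra
}

#' Distribution-level tests on per-gene correlation sets
#'
#' Per time point, a Lilliefors (Kolmogorov-Smirnov) normality test of the
#' gene-level correlation distribution; across time-point pairs, two-sample
#' t-tests of means and F-tests of variances.
#'
#' @param records output of [paired_correlations()].
#' @return list with `normality` (per time point: statistic, p) and
#'   `pairwise` (per pair: `t_p`, `f_p`).
#' @export
correlation_distribution_tests <- function(records) {
  records <- records[!is.na(records$rho), , drop = FALSE]
  tps <- sort(unique(records$time_point_hr))
  norm_rows <- lapply(tps, function(tp) {
    x <- records$rho[records$time_point_hr == tp]
    if (length(x) < 4) {
      return(data.frame(time_point_hr = tp, statistic = NA_real_,
                        p_value = NA_real_, n = length(x)))
    }
    lt <- nortest::lillie.test(x)
    data.frame(time_point_hr = tp, statistic = unname(lt$statistic),
               p_value = lt$p.value, n = length(x))
  })
  pair_rows <- list()
  if (length(tps) >= 2) {
    for (a in seq_len(length(tps) - 1)) {
      for (b in seq(a + 1, length(tps))) {
        xa <- records$rho[records$time_point_hr == tps[a]]
        xb <- records$rho[records$time_point_hr == tps[b]]
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          time_a = tps[a], time_b = tps[b],
          t_p = tryCatch(stats::t.test(xa, xb)$p.value,
                         error = function(e) NA_real_),
          f_p = tryCatch(stats::var.test(xa, xb)$p.value,
                         error = function(e) NA_real_))
      }
    }
  }
  list(normality = do.call(rbind, norm_rows),
       pairwise = do.call(rbind, pair_rows))
}

#' Coefficient of variation of a target at a time point
#'
#' Sample sd over mean of delta-Ct across the retained cells of the time
#' point; zeros are included unless `detected_only = TRUE`.
#'
#' @param dct a [delta_ct_table()].
#' @param target target id.
#' @param time_point time point (hours).
#' @param detected_only restrict to cells with delta-Ct > 0.
#' @return the CV, or `NA` (attribute `undefined = TRUE`) when the mean is 0.
#' @export
coefficient_of_variation <- function(dct, target, time_point,
                                     detected_only = FALSE) {
  stopifnot(inherits(dct, "DeltaCtTable"))
  sub <- cells_only(dct, time_point)
  x <- sub$dct[, target]
  if (detected_only) x <- x[x > 0]
  if (!length(x) || mean(x) == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  stats::sd(x) / mean(x)
}

#' Matched empirical quantiles of two samples
#'
#' Quantiles of both samples at `n_quantiles` probabilities
#' `(i - 0.5) / n_quantiles` (type-4/linear interpolation convention,
#' [stats::quantile()] type 7 on those probabilities), paired for Q-Q
#' plotting.
#'
#' @param sample_a,sample_b numeric vectors.
#' @param n_quantiles number of probability points, default 99.
#' @return data.frame: `prob`, `q_a`, `q_b`.
#' @export
qq_curve <- function(sample_a, sample_b, n_quantiles = 99) {
  stopifnot(length(sample_a) > 0, length(sample_b) > 0, n_quantiles >= 1)
  p <- (seq_len(n_quantiles) - 0.5) / n_quantiles
  data.frame(prob = p,
             q_a = unname(stats::quantile(sample_a, p, type = 7)),
             q_b = unname(stats::quantile(sample_b, p, type = 7)))
}
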