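#' Quadrant detection profiles per gene
#'
#' Every cell is binned, per gene with both analytes, into one of four
#' joint-detection quadrants — P-R-, P-R+, P+R+, P+R- (protein then RNA)
#' — using each target's detection threshold. The profile is the fraction
#' of cells in each quadrant per time point.
#'
#' RNA targets have no zero-cell background wells, so their detection
#' defaults to delta-Ct > 0 unless a threshold is supplied for them.
#'
#' @param dct a [delta_ct_table()] of retained cells.
#' @param genes genes to profile; default all complete pairs.
#' @param thresholds optional [detection_threshold()] data.frame; targets
#'   absent from it use threshold 0.
#' @return data.frame: `gene`, `time_point_hr`, `n_cells`, and the four
#'   proportions `p_neg_r_neg`, `p_neg_r_pos`, `p_pos_r_pos`,
#'   `p_pos_r_neg` (each row's four proportions sum to 1).
#' @export
quadrant_profiles <- function(dct, genes = NULL, thresholds = NULL) {
  stopifnot(inherits(dct, "DeltaCtTable"))
  pairs <- paired_targets(dct, genes)
  tps <- sort(unique(dct$wells$time_point_hr[dct$wells$sample_type == "CELL"]))
  rows <- list()
  for (g in seq_len(nrow(pairs))) {
    thr_r <- threshold_for(thresholds, pairs$rna[g])
    thr_p <- threshold_for(thresholds, pairs$protein[g])
    for (tp in tps) {
      sub <- cells_only(dct, tp)
      n <- nrow(sub$dct)
      if (!n) next
      r <- call_detection(sub$dct[, pairs$rna[g]], thr_r)
      p <- call_detection(sub$dct[, pairs$protein[g]], thr_p)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = pairs$gene[g], time_point_hr = tp, n_cells = n,
        p_neg_r_neg = mean(!p & !r), p_neg_r_pos = mean(!p & r),
        p_pos_r_pos = mean(p & r), p_pos_r_neg = mean(p & !r),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Cluster genes by their quadrant trajectories
#'
#' Each gene's quadrant proportions are concatenated across time points
#' (time ascending, quadrants in the fixed P-R-, P-R+, P+R+, P+R- order)
#' into one profile vector; genes are clustered by average-linkage
#' hierarchical clustering on `1 - Spearman rho` between profile vectors
#' and partitioned at `cut_height`. A gene with a constant profile has no
#' rank ordering to correlate and is assigned its own singleton cluster.
#'
#' @param profiles output of [quadrant_profiles()].
#' @param cut_height dendrogram cut on the `1 - rho` scale, default 0.75.
#' @return list of class `trajectory_clustering`: `genes`, `dist`
#'   (gene x gene matrix of `1 - rho`), `hclust` (`NULL` when < 2
#'   clusterable genes), `cluster` (named integer vector).
#' @export
cluster_trajectories <- function(profiles, cut_height = 0.75) {
  qcols <- c("p_neg_r_neg", "p_neg_r_pos", "p_pos_r_pos", "p_pos_r_neg")
  stopifnot(all(qcols %in% names(profiles)))
  genes <- sort(unique(profiles$gene))
  if (length(genes) < 1) stop("no genes to cluster", call. = FALSE)
  tps <- sort(unique(profiles$time_point_hr))
  vecs <- t(vapply(genes, function(g) {
    sub <- profiles[profiles$gene == g, , drop = FALSE]
    sub <- sub[match(tps, sub$time_point_hr), , drop = FALSE]
    as.numeric(t(as.matrix(sub[, qcols])))
  }, numeric(4 * length(tps))))
  rownames(vecs) <- genes
  const <- apply(vecs, 1, stats::sd) == 0
  if (any(const)) {
    warning("constant profile(s) placed in singleton clusters: ",
            paste(genes[const], collapse = ", "))
  }
  use <- genes[!const]
  cluster <- stats::setNames(integer(length(genes)), genes)
  hc <- NULL
  if (length(use) >= 2) {
    cm <- stats::cor(t(vecs[use, , drop = FALSE]), method = "spearman")
    d <- 1 - cm
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    cl <- stats::cutree(hc, h = cut_height)
    cluster[use] <- cl[use]
  } else if (length(use) == 1) {
    cluster[use] <- 1L
  }
  nxt <- max(cluster) + 1L
  for (g in genes[const]) {
    cluster[g] <- nxt
    nxt <- nxt + 1L
  }
  dmat <- matrix(NA_real_, length(genes), length(genes),
                 dimnames = list(genes, genes))
  if (length(use) >= 2) {
    dmat[use, use] <- 1 - stats::cor(t(vecs[use, , drop = FALSE]),
                                     method = "spearman")
  }
  diag(dmat) <- 0
  structure(list(genes = genes, profile_vectors = vecs, dist = dmat,
                 hclust = hc, cluster = cluster, cut_height = cut_height),
            class = "trajectory_clustering")
}

#' @export
print.trajectory_clustering <- function(x, ...) {
  cat("trajectory clustering:", length(x$genes), "genes,",
      length(unique(x$cluster)), "clusters at cut", x$cut_height, "\n")
  invisible(x)
}
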