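#' Permutation null for pairwise Spearman correlations
#'
#' For each target pair, one margin's cell labels are permuted
#' `n_permutations` times and the Spearman correlation recorded; the mean
#' and variance of that null distribution calibrate the edge threshold.
#'
#' @param dct a [delta_ct_table()] of retained cells (>= 10).
#' @param pairs two-column matrix or data.frame of target ids; default all
#'   unordered pairs.
#' @param n_permutations label mixes per pair, default 10000.
#' @param seed RNG seed.
#' @return data.frame: `target_a`, `target_b`, `null_mean`, `null_var`,
#'   `n_permutations`; pairs with a constant margin are excluded with a
#'   warning.
#' @export
pairwise_permutation_null <- function(dct, pairs = NULL,
                                      n_permutations = 10000, seed = 1L) {
  stopifnot(inherits(dct, "DeltaCtTable"))
  cells <- cells_only(dct)
  n <- nrow(cells$dct)
  if (n < 10) stop("need >= 10 cells", call. = FALSE)
  ids <- cells$targets$target_id
  if (is.null(pairs)) {
    pairs <- t(utils::combn(ids, 2))
  }
  pairs <- as.matrix(pairs)
  set.seed(seed)
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    x <- cells$dct[, a]; y <- cells$dct[, b]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("pair ", a, " / ", b, " has a constant margin; excluded")
      next
    }
    rx <- rank(x); ry <- rank(y)
    null <- vapply(seq_len(n_permutations), function(i) {
      stats::cor(rx[sample.int(n)], ry)
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      target_a = a, target_b = b, null_mean = mean(null),
      null_var = stats::var(null), n_permutations = n_permutations,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no non-degenerate pairs", call. = FALSE)
  do.call(rbind, rows)
}

#' Correlation edge threshold from permutation-null parameters
#'
#' The Spearman correlation above which an edge has probability `alpha` of
#' being drawn from the null: `null_mean + qnorm(1 - alpha) * sqrt(null_var)`.
#'
#' @param null_mean,null_var null-distribution mean and variance.
#' @param alpha tail probability, default 0.01.
#' @return the threshold (unitless rho).
#' @export
edge_threshold <- function(null_mean, null_var, alpha = 0.01) {
  stopifnot(null_var >= 0, alpha > 0, alpha < 1)
  null_mean + stats::qnorm(1 - alpha) * sqrt(null_var)
}

#' Grow a correlation network from a seed target set
#'
#' At one time point, every non-seed target's Spearman correlation against
#' each seed-network member is computed; correlations strictly greater than
#' the threshold are edges, and a target's edge degree is its number of
#' edges into the seed network.
#'
#' @param dct a [delta_ct_table()] of retained cells.
#' @param seed_targets character vector of seed target ids.
#' @param time_point time point (hours) whose cells are used.
#' @param rho_threshold edge threshold, default 0.3.
#' @return list of class `correlation_network`: `time_point_hr`,
#'   `seed_targets`, `edges` (data.frame `target`, `seed`, `rho`),
#'   `edge_degree` (named integer vector over non-seed targets).
#' @export
grow_seed_network <- function(dct, seed_targets, time_point,
                              rho_threshold = 0.3) {
  stopifnot(inherits(dct, "DeltaCtTable"))
  miss <- setdiff(seed_targets, dct$targets$target_id)
  if (length(miss)) {
    stop("seed target(s) absent: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cells <- cells_only(dct, time_point)
  keep_seed <- seed_targets[vapply(seed_targets, function(s) {
    ok <- stats::sd(cells$dct[, s]) > 0
    if (!ok) warning("seed target ", s, " constant at ", time_point,
                     " hr; excluded")
    ok
  }, logical(1))]
  if (!length(keep_seed)) stop("no usable seed targets", call. = FALSE)
  others <- setdiff(cells$targets$target_id, seed_targets)
  edges <- list()
  degree <- stats::setNames(integer(length(others)), others)
  for (tg in others) {
    x <- cells$dct[, tg]
    if (stats::sd(x) == 0) next
    for (s in keep_seed) {
      rho <- stats::cor(x, cells$dct[, s], method = "spearman")
      if (!is.na(rho) && rho > rho_threshold) {
        edges[[length(edges) + 1L]] <- data.frame(
          target = tg, seed = s, rho = rho, stringsAsFactors = FALSE)
        degree[tg] <- degree[tg] + 1L
      }
    }
  }
  structure(list(time_point_hr = time_point, seed_targets = keep_seed,
                 edges = if (length(edges)) do.call(rbind, edges)
                         else data.frame(target = character(0),
                                         seed = character(0),
                                         rho = numeric(0)),
                 edge_degree = degree, rho_threshold = rho_threshold),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation network at %g hr: %d seed targets, %d edges, %d connected targets\n",
              x$time_point_hr, length(x$seed_targets), nrow(x$edges),
              sum(x$edge_degree > 0)))
  invisible(x)
}

#' Cluster cells over a circuit and test cluster enrichment
#'
#' Each circuit target is scaled so its maximum over cells is 1; cells are
#' then correlated (Spearman) against each other across the circuit,
#' hierarchically clustered (average linkage on 1 - correlation) and cut
#' into `k_clusters`. Fisher's exact tests ask whether cluster membership
#' associates with detection of a gate target and with time point.
#'
#' @param dct a [delta_ct_table()] of retained cells.
#' @param circuit_targets >= 2 target ids forming the circuit.
#' @param gate_target target whose detection is tested against clusters.
#' @param k_clusters number of flat clusters, default 2.
#' @param threshold detection threshold (cycles) for the gate target.
#' @param method correlation estimator for the cell-cell matrix,
#'   `"spearman"` (default) or `"pearson"`.
#' @return list of class `circuit_clustering`: `cells`, `scaled`
#'   (cells x targets), `cell_cor`, `cluster` (named integer vector),
#'   `gate_fisher_p`, `time_fisher_p`, `hclust`.
#' @export
circuit_cell_clustering <- function(dct, circuit_targets, gate_target,
                                    k_clusters = 2, threshold = 0,
                                    method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(dct, "DeltaCtTable"), length(circuit_targets) >= 2)
  cells <- cells_only(dct)
  if (nrow(cells$dct) < k_clusters) stop("fewer cells than clusters",
                                         call. = FALSE)
  m <- cells$dct[, circuit_targets, drop = FALSE]
  mx <- apply(m, 2, max)
  drop <- mx == 0
  if (any(drop)) {
    warning("all-zero circuit target(s) dropped: ",
            paste(circuit_targets[drop], collapse = ", "))
    m <- m[, !drop, drop = FALSE]
    if (ncol(m) < 2) stop("fewer than 2 usable circuit targets", call. = FALSE)
    mx <- mx[!drop]
  }
  scaled <- sweep(m, 2, mx, `/`)
  cc <- suppressWarnings(stats::cor(t(scaled), method = method))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  cl <- stats::cutree(hc, k = k_clusters)
  gate_det <- call_detection(cells$dct[, gate_target],
                             if (is.data.frame(threshold))
                               threshold$threshold_dct[
                                 threshold$target_id == gate_target]
                             else threshold)
  gate_p <- fisher_or_na(table(factor(cl), factor(gate_det,
                                                  levels = c(FALSE, TRUE))))
  time_p <- fisher_or_na(table(factor(cl),
                               factor(cells$wells$time_point_hr)))
  structure(list(cells = cells$wells$well_id, scaled = scaled,
                 cell_cor = cc, cluster = cl, hclust = hc,
                 gate_fisher_p = gate_p, time_fisher_p = time_p),
            class = "circuit_clustering")
}

fisher_or_na <- function(tab) {
  if (any(dim(tab) < 2)) return(NA_real_)
  tryCatch(stats::fisher.test(tab)$p.value, error = function(e) NA_real_)
}
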