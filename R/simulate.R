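#' Per-gene generative parameters for paired single-cell expression
#'
#' One row per gene x time point, describing the bimodal single-cell
#' expression of the RNA and protein assay of that gene: a detected fraction
#' `pi` and a normal expressing component on the delta-Ct scale, plus a
#' latent Gaussian-copula coupling `pair_rho` between the two analytes.
#'
#' @param gene gene symbol shared by the paired assays.
#' @param time_point_hr time point in hours.
#' @param pi_rna,pi_protein fraction of cells in which the analyte is detected.
#' @param mu_rna,mu_protein mean delta-Ct of expressing cells (cycles).
#' @param sigma_rna,sigma_protein sd of expressing cells' delta-Ct (cycles).
#' @param pair_rho latent RNA-protein coupling in `[-1, 1]`.
#' @return data.frame with one row per gene x time point.
#' @export
gene_gen_params <- function(gene, time_point_hr,
                            pi_rna, mu_rna, sigma_rna,
                            pi_protein, mu_protein, sigma_protein,
                            pair_rho = 0) {
  p <- data.frame(gene = gene, time_point_hr = time_point_hr,
                  pi_rna = pi_rna, mu_rna = mu_rna, sigma_rna = sigma_rna,
                  pi_protein = pi_protein, mu_protein = mu_protein,
                  sigma_protein = sigma_protein, pair_rho = pair_rho,
                  stringsAsFactors = FALSE)
  with(p, stopifnot(all(pi_rna >= 0 & pi_rna <= 1),
                    all(pi_protein >= 0 & pi_protein <= 1),
                    all(sigma_rna > 0), all(sigma_protein > 0),
                    all(abs(pair_rho) <= 1)))
  p
}

#' Simulate a paired protein + RNA single-cell qPCR study
#'
#' For each cell and gene a latent bivariate standard normal with correlation
#' `pair_rho` is drawn. Each margin is detected when its latent value lies in
#' the upper `pi` tail; detected margins map, through the conditional latent
#' quantile, to a delta-Ct from a Normal(mu, sigma) truncated to
#' `(0, ceiling]` — so detection and level co-vary the way bimodal
#' single-cell data do while the margins stay exact. Delta-Ct is then
#' back-converted to raw Ct (RNA: `ct_ceiling - dct`; protein:
#' `bg_mean_ct - dct`), undetected reactions become the sentinel, and
#' zero-cell wells receive protein background draws
#' `Normal(bg_mean_ct, bg_sd_ct)`.
#'
#' @param params data.frame from [gene_gen_params()] covering every gene at
#'   every requested time point.
#' @param n_cells named numeric vector: cells per time point (names are the
#'   time points in hours).
#' @param background data.frame with columns `gene`, `bg_mean_ct`,
#'   `bg_sd_ct` for each gene's protein assay, or a single pair of numbers
#'   recycled to all genes.
#' @param n_zero_cell named numeric vector like `n_cells`: zero-cell wells
#'   per time point (default 5 each).
#' @param seed integer RNG seed.
#' @param ct_ceiling Ct ceiling (cycles), default 24.
#' @return list with elements `ct` (a [ct_table()]) and `truth` (generating
#'   parameters, per-cell latent detection indicators and the seed).
#' @export
generate_single_cell_study <- function(params, n_cells, background,
                                       n_zero_cell = NULL, seed = 1L,
                                       ct_ceiling = 24) {
  stopifnot(nrow(params) >= 1, all(n_cells >= 1))
  if (any(params$pi_rna < 0 | params$pi_rna > 1 |
          params$pi_protein < 0 | params$pi_protein > 1)) {
    stop("pi_detect must lie in [0, 1]", call. = FALSE)
  }
  tps <- as.numeric(names(n_cells))
  if (anyNA(tps)) stop("n_cells must be named by time point", call. = FALSE)
  genes <- unique(params$gene)
  if (is.numeric(background)) {
    background <- data.frame(gene = genes, bg_mean_ct = background[1],
                             bg_sd_ct = background[2])
  }
  if (length(miss <- setdiff(genes, background$gene))) {
    stop("background parameters missing for gene(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(n_zero_cell)) {
    n_zero_cell <- stats::setNames(rep(5, length(tps)), names(n_cells))
  }

  set.seed(seed)
  target_ids <- c(rbind(paste0(genes, "_R"), paste0(genes, "_P")))
  targets <- data.frame(
    target_id = target_ids,
    analyte = rep(c("RNA", "PROTEIN"), times = length(genes)),
    gene = rep(genes, each = 2), stringsAsFactors = FALSE)

  well_rows <- list(); ct_rows <- list(); latent_rows <- list()
  cell_idx <- 0L
  for (ti in seq_along(tps)) {
    tp <- tps[ti]
    n <- n_cells[ti]
    ptp <- params[params$time_point_hr == tp, , drop = FALSE]
    if (length(miss <- setdiff(genes, ptp$gene))) {
      stop("params missing gene(s) at time ", tp, ": ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    ptp <- ptp[match(genes, ptp$gene), , drop = FALSE]
    ct <- matrix(NA_real_, n, length(target_ids),
                 dimnames = list(NULL, target_ids))
    det <- matrix(FALSE, n, length(target_ids),
                  dimnames = list(NULL, target_ids))
    for (g in seq_along(genes)) {
      pr <- ptp[g, ]
      bg <- background[background$gene == genes[g], ][1, ]
      # latent bivariate standard normal (Gaussian copula)
      z1 <- stats::rnorm(n)
      z2 <- pr$pair_rho * z1 + sqrt(1 - pr$pair_rho^2) * stats::rnorm(n)
      dct_r <- latent_to_dct(z1, pr$pi_rna, pr$mu_rna, pr$sigma_rna,
                             hi = ct_ceiling)
      dct_p <- latent_to_dct(z2, pr$pi_protein, pr$mu_protein,
                             pr$sigma_protein,
                             hi = min(ct_ceiling, bg$bg_mean_ct))
      rid <- paste0(genes[g], "_R"); pid <- paste0(genes[g], "_P")
      ct[, rid] <- ifelse(is.na(dct_r), NA, ct_ceiling - dct_r)
      ct[, pid] <- ifelse(is.na(dct_p), NA, bg$bg_mean_ct - dct_p)
      det[, rid] <- !is.na(dct_r); det[, pid] <- !is.na(dct_p)
    }
    ids <- sprintf("cell_t%g_%03d", tp, seq_len(n))
    rownames(ct) <- ids; rownames(det) <- ids
    well_rows[[length(well_rows) + 1L]] <- data.frame(
      well_id = ids, sample_type = "CELL", time_point_hr = tp,
      n_cells_captured = 1L, dilution_quantity = NA_real_)
    ct_rows[[length(ct_rows) + 1L]] <- ct
    latent_rows[[length(latent_rows) + 1L]] <- det
    cell_idx <- cell_idx + n

    nz <- n_zero_cell[ti]
    if (nz > 0) {
      zct <- matrix(NA_real_, nz, length(target_ids),
                    dimnames = list(NULL, target_ids))
      for (g in seq_along(genes)) {
        bg <- background[background$gene == genes[g], ][1, ]
        zct[, paste0(genes[g], "_P")] <-
          stats::rnorm(nz, bg$bg_mean_ct, bg$bg_sd_ct)
      }
      zids <- sprintf("zero_t%g_%03d", tp, seq_len(nz))
      rownames(zct) <- zids
      well_rows[[length(well_rows) + 1L]] <- data.frame(
        well_id = zids, sample_type = "ZERO_CELL", time_point_hr = tp,
        n_cells_captured = 0L, dilution_quantity = NA_real_)
      ct_rows[[length(ct_rows) + 1L]] <- zct
    }
  }
  wells <- do.call(rbind, well_rows)
  ct <- do.call(rbind, ct_rows)
  truth <- list(params = params, background = background,
                n_cells = n_cells, n_zero_cell = n_zero_cell,
                detected = do.call(rbind, latent_rows),
                seed = seed, ct_ceiling = ct_ceiling)
  list(ct = ct_table(ct, wells, targets), truth = truth)
}

# Map latent standard-normal values to delta-Ct: upper-pi tail detected,
# detected quantile pushed through the truncated-normal inverse CDF so the
# detected margin is exactly Normal(mu, sigma) truncated to (0, hi].
latent_to_dct <- function(z, pi_detect, mu, sigma, hi) {
  out <- rep(NA_real_, length(z))
  if (pi_detect <= 0) return(out)
  cut <- stats::qnorm(1 - pi_detect)
  det <- z > cut
  if (!any(det)) return(out)
  u <- (stats::pnorm(z[det]) - (1 - pi_detect)) / pi_detect
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  p_lo <- stats::pnorm(0, mu, sigma)
  p_hi <- stats::pnorm(hi, mu, sigma)
  out[det] <- stats::qnorm(p_lo + u * (p_hi - p_lo), mu, sigma)
  out
}

#' Simulate a dilution standard-curve plate for one assay
#'
#' Generates `n_replicates` wells at each quantity. Inside the true linear
#' window `[linear_lo, linear_hi]` (indices into `quantities`) the mean
#' delta-Ct is `intercept + slope * log2(quantity)`; below the window the
#' signal sits at background (delta-Ct 0); above it, when `hook = TRUE`,
#' signal declines with quantity (the PEA hook effect). Delta-Ct is
#' back-converted to Ct against the background mean, and 8 lysis-buffer
#' wells are drawn from the background distribution.
#'
#' @param quantities positive quantities (cell equivalents or molecules) in
#'   strictly monotone order.
#' @param slope cycles per doubling inside the linear window.
#' @param intercept cycles, delta-Ct at `log2(quantity) = 0`.
#' @param noise_sd replicate noise sd (cycles).
#' @param linear_lo,linear_hi 1-based inclusive indices into `quantities`
#'   bounding the true linear window.
#' @param hook if `TRUE`, delta-Ct declines above `linear_hi`.
#' @param n_replicates replicate wells per quantity (default 8).
#' @param bg_mean_ct,bg_sd_ct background Ct distribution for lysis-buffer
#'   wells and for back-conversion.
#' @param target_id,analyte,gene assay identity for the generated table.
#' @param seed integer RNG seed.
#' @return list with elements `ct` (a [ct_table()] of DILUTION plus
#'   LYSIS_BUFFER wells) and `truth` (generating parameters incl. the true
#'   per-level mean delta-Ct).
#' @export
generate_dilution_series <- function(quantities, slope, intercept,
                                     noise_sd = 0.1,
                                     linear_lo = 1L,
                                     linear_hi = length(quantities),
                                     hook = FALSE, n_replicates = 8L,
                                     bg_mean_ct = 22, bg_sd_ct = 0.3,
                                     target_id = "SIM_P",
                                     analyte = "PROTEIN", gene = "SIM",
                                     seed = 1L) {
  if (length(quantities) < 3) {
    stop("need at least 3 dilution quantities", call. = FALSE)
  }
  if (n_replicates < 2) stop("need n_replicates >= 2", call. = FALSE)
  stopifnot(all(quantities > 0), linear_lo <= linear_hi,
            linear_lo >= 1, linear_hi <= length(quantities))
  d <- diff(quantities)
  if (!(all(d > 0) || all(d < 0))) {
    stop("quantities must be strictly monotone", call. = FALSE)
  }
  set.seed(seed)
  nlev <- length(quantities)
  # the window is stated as indices; its semantics live on the quantity axis:
  # flat background below the window's smallest quantity, saturation (or the
  # hook decline) above its largest
  q_win <- range(quantities[linear_lo:linear_hi])
  lq_top <- log2(q_win[2])
  mean_dct <- numeric(nlev)
  for (i in seq_len(nlev)) {
    lq <- log2(quantities[i])
    if (quantities[i] < q_win[1]) {
      mean_dct[i] <- 0
    } else if (quantities[i] <= q_win[2]) {
      mean_dct[i] <- intercept + slope * lq
    } else if (hook) {
      mean_dct[i] <- intercept + slope * lq_top - abs(slope) * (lq - lq_top)
    } else {
      mean_dct[i] <- intercept + slope * lq_top
    }
  }
  mean_dct <- pmax(mean_dct, 0)

  well_id <- character(0); qty <- numeric(0); ct <- numeric(0)
  for (i in seq_len(nlev)) {
    dct <- mean_dct[i] + stats::rnorm(n_replicates, 0, noise_sd)
    ct <- c(ct, bg_mean_ct - dct)
    qty <- c(qty, rep(quantities[i], n_replicates))
    well_id <- c(well_id, sprintf("dil_%02d_%02d", i, seq_len(n_replicates)))
  }
  n_buf <- 8L
  buf_ct <- stats::rnorm(n_buf, bg_mean_ct, bg_sd_ct)
  wells <- data.frame(
    well_id = c(well_id, sprintf("buf_%02d", seq_len(n_buf))),
    sample_type = c(rep("DILUTION", length(well_id)),
                    rep("LYSIS_BUFFER", n_buf)),
    time_point_hr = NA_real_,
    n_cells_captured = 0L,
    dilution_quantity = c(qty, rep(NA_real_, n_buf)))
  m <- matrix(c(ct, buf_ct), ncol = 1,
              dimnames = list(wells$well_id, target_id))
  targets <- data.frame(target_id = target_id, analyte = analyte,
                        gene = gene, stringsAsFactors = FALSE)
  truth <- list(quantities = quantities, slope = slope,
                intercept = intercept, noise_sd = noise_sd,
                linear_lo = linear_lo, linear_hi = linear_hi,
                hook = hook, n_replicates = n_replicates,
                mean_dct = mean_dct, bg_mean_ct = bg_mean_ct,
                bg_sd_ct = bg_sd_ct, seed = seed)
  list(ct = ct_table(m, wells, targets), truth = truth)
}
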