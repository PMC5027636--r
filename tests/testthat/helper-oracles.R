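# Independent oracles used to cross-check the implementation. These are
# deliberately written with different machinery than the package code.

# Brute-force contiguous-window search using stats::lm, with the same
# objective (r2 - cost * removed) and tie-breaks (longer window, earlier
# start).
oracle_linear_range <- function(quantities, means, cost) {
  n <- length(means)
  lx <- log2(quantities)
  best <- NULL
  for (lo in seq_len(n - 2)) {
    for (hi in seq(lo + 2, n)) {
      y <- means[lo:hi]
      if (var(y) == 0) {
        r2 <- 0
      } else {
        # summary.lm warns on perfect fits; irrelevant for the oracle
        r2 <- suppressWarnings(summary(stats::lm(y ~ lx[lo:hi]))$r.squared)
      }
      len <- hi - lo + 1
      score <- r2 - cost * (n - len)
      cand <- list(lo = lo, hi = hi, len = len, score = score, r2 = r2)
      if (is.null(best) || score > best$score ||
          (score == best$score && len > best$len) ||
          (score == best$score && len == best$len && lo < best$lo)) {
        best <- cand
      }
    }
  }
  best
}

# Exact two-sided Fisher p by enumerating the hypergeometric support with
# the usual "at most as probable as observed" rule (relative tolerance as
# in stats::fisher.test).
oracle_fisher_p <- function(tab) {
  m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  support <- max(0, k - n):min(k, m)
  dens <- dhyper(support, m, n, k)
  obs <- dhyper(tab[1, 1], m, n, k)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by complete enumeration of group
# assignments (no ties assumed), matching the doubled-tail convention.
oracle_mwu_p <- function(xa, xb) {
  pooled <- c(xa, xb)
  stopifnot(!anyDuplicated(pooled))
  na <- length(xa)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(length(pooled), na)
  us <- apply(combs, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  mid <- na * length(xb) / 2
  if (u_obs > mid) {
    p <- 2 * mean(us >= u_obs)
  } else if (u_obs < mid) {
    p <- 2 * mean(us <= u_obs)
  } else {
    p <- 1
  }
  min(1, p)
}

# Manual Spearman via the classical no-ties formula.
oracle_spearman_no_ties <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Build a dilution_series object directly from level means (replicated with
# optional jitter), bypassing the table machinery.
make_series <- function(quantities, means, n_rep = 2, jitter = 0,
                        target_id = "T_P") {
  m <- matrix(rep(means, n_rep), ncol = n_rep)
  if (jitter > 0) m <- m + matrix(rnorm(length(m), 0, jitter), nrow(m))
  rownames(m) <- as.character(quantities)
  structure(list(target_id = target_id, quantities = quantities, dct = m),
            class = "dilution_series")
}

# Small two-gene paired study used by several suites.
make_small_study <- function(seed = 1, n = c("0" = 40, "24" = 40),
                             pair_rho = 0.5, pi_rna = 0.9, pi_protein = 0.7) {
  genes <- c("MET", "CASP8")
  params <- do.call(rbind, lapply(as.numeric(names(n)), function(tp) {
    gene_gen_params(genes, tp, pi_rna = pi_rna, mu_rna = 8, sigma_rna = 2,
                    pi_protein = pi_protein, mu_protein = 5,
                    sigma_protein = 1.5, pair_rho = pair_rho)
  }))
  generate_single_cell_study(params, n, background = c(20, 0.4), seed = seed)
}

# Normalize a generated study into a combined delta-Ct table.
normalize_study <- function(sim, ct_ceiling = 24) {
  bg <- estimate_protein_background(sim$ct, ct_ceiling)
  combine_targets(rna_delta_ct(sim$ct, ct_ceiling),
                  protein_delta_ct(sim$ct, bg, ct_ceiling))
}
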