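test_that("edge threshold reproduces its closed form", {
  # null mean 0.005, variance 0.015 at alpha 0.01 -> 0.29 to 2 d.p.
  expect_equal(round(edge_threshold(0.005, 0.015, 0.01), 2), 0.29)
  # z = 0 at alpha 0.5
  expect_equal(edge_threshold(0.12, 0.02, 0.5), 0.12)
  # z = 1 at alpha = 1 - pnorm(1)
  expect_equal(edge_threshold(0, 0.01, 1 - pnorm(1)), 0.10, tolerance = 1e-9)
  expect_error(edge_threshold(0, -1, 0.01))
})

test_that("permutation null summaries are centered, sized and reproducible", {
  sim <- make_small_study(seed = 14, n = c("0" = 70))
  dct <- normalize_study(sim)
  ids <- c("MET_R", "MET_P", "CASP8_R")
  nul <- pairwise_permutation_null(dct, pairs = cbind(ids[c(1, 1)],
                                                      ids[c(2, 3)]),
                                   n_permutations = 10000, seed = 3)
  expect_equal(nrow(nul), 2)
  expect_true(all(abs(nul$null_mean) < 0.02))
  # asymptotic Spearman null variance is about 1/(n-1)
  expect_true(all(abs(nul$null_var - 1 / 69) < 0.5 / 69))

  nul2 <- pairwise_permutation_null(dct, pairs = cbind(ids[c(1, 1)],
                                                       ids[c(2, 3)]),
                                    n_permutations = 10000, seed = 3)
  expect_identical(nul, nul2)

  # constant margin is excluded with a warning; nothing left is an error
  dct$dct[, "CASP8_R"] <- 0
  expect_warning(expect_error(
    pairwise_permutation_null(dct, pairs = cbind("MET_R", "CASP8_R"),
                              n_permutations = 10),
    "non-degenerate"), "constant")
})

test_that("seed networks collect strict-threshold edges with degrees", {
  set.seed(15)
  n <- 200
  wells <- data.frame(well_id = sprintf("c%03d", 1:n), sample_type = "CELL",
                      time_point_hr = 0, n_cells_captured = 1,
                      dilution_quantity = NA_real_)
  targets <- data.frame(target_id = c("S1", "S2", "B1", "B2", "I1"),
                        analyte = "RNA",
                        gene = c("s1", "s2", "b1", "b2", "i1"))
  base <- rnorm(n)
  m <- cbind(S1 = base + rnorm(n, 0, 0.5),
             S2 = rnorm(n),
             B1 = base + rnorm(n, 0, 0.5),   # correlated with S1
             B2 = base + rnorm(n, 0, 0.5),   # correlated with S1
             I1 = rnorm(n))                  # independent
  m <- m - min(m)
  rownames(m) <- wells$well_id
  dct <- delta_ct_table(m, wells, targets)
  net <- grow_seed_network(dct, c("S1", "S2"), 0, rho_threshold = 0.3)
  expect_true(all(c("B1", "B2") %in% net$edges$target))
  expect_gte(net$edge_degree[["B1"]], 1)
  expect_equal(net$edge_degree[["I1"]], 0)
  expect_true(all(net$edges$rho > 0.3))

  # monotone in the threshold: raising it never adds an edge
  net2 <- grow_seed_network(dct, c("S1", "S2"), 0, rho_threshold = 0.5)
  expect_lte(nrow(net2$edges), nrow(net$edges))
  expect_true(all(paste(net2$edges$target, net2$edges$seed) %in%
                  paste(net$edges$target, net$edges$seed)))

  # boundary: rho exactly at the threshold is not an edge
  w2 <- wells[1:4, ]
  t2 <- data.frame(target_id = c("X", "Y"), analyte = "RNA",
                   gene = c("x", "y"))
  m2 <- cbind(X = c(1, 2, 3, 4), Y = c(1, 2, 4, 3))  # rho = 0.8
  rownames(m2) <- w2$well_id
  d2 <- delta_ct_table(m2, w2, t2)
  expect_equal(nrow(grow_seed_network(d2, "X", 0, 0.8)$edges), 0)
  expect_equal(nrow(grow_seed_network(d2, "X", 0, 0.79)$edges), 1)
  expect_error(grow_seed_network(d2, "Z", 0), "absent")
})

test_that("block structure reliably connects to the seed across seeds", {
  hits <- 0L
  for (seed in 1:40) {
    set.seed(seed)
    n <- 200
    base <- rnorm(n)
    m <- cbind(SEED = base + rnorm(n, 0, 0.6),
               M1 = base + rnorm(n, 0, 0.6),
               M2 = base + rnorm(n, 0, 0.6),
               OT = rnorm(n))
    m <- m - min(m)
    wells <- data.frame(well_id = sprintf("c%03d", 1:n),
                        sample_type = "CELL", time_point_hr = 0,
                        n_cells_captured = 1, dilution_quantity = NA_real_)
    targets <- data.frame(target_id = colnames(m), analyte = "RNA",
                          gene = tolower(colnames(m)))
    rownames(m) <- wells$well_id
    net <- grow_seed_network(delta_ct_table(m, wells, targets), "SEED", 0)
    if (all(c("M1", "M2") %in% net$edges$target)) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
})

test_that("circuit clustering scales targets, recovers blocks and tests enrichment", {
  set.seed(16)
  n_per <- 30
  wells <- data.frame(well_id = sprintf("c%03d", 1:(2 * n_per)),
                      sample_type = "CELL",
                      time_point_hr = rep(c(0, 24), each = n_per),
                      n_cells_captured = 1, dilution_quantity = NA_real_)
  targets <- data.frame(target_id = sprintf("T%d", 1:4), analyte = "RNA",
                        gene = sprintf("t%d", 1:4))
  # two cell blocks with opposite signatures over the circuit
  m <- rbind(cbind(rnorm(n_per, 8, 0.5), rnorm(n_per, 8, 0.5),
                   rnorm(n_per, 1, 0.3), rnorm(n_per, 1, 0.3)),
             cbind(rnorm(n_per, 1, 0.3), rnorm(n_per, 1, 0.3),
                   rnorm(n_per, 8, 0.5), rnorm(n_per, 8, 0.5)))
  m <- pmax(m, 0)
  dimnames(m) <- list(wells$well_id, targets$target_id)
  dct <- delta_ct_table(m, wells, targets)
  cl <- circuit_cell_clustering(dct, targets$target_id, gate_target = "T1")
  expect_equal(apply(cl$scaled, 2, max), setNames(rep(1, 4),
                                                  targets$target_id))
  # clusters recover the two blocks exactly
  expect_equal(length(unique(cl$cluster[1:n_per])), 1)
  expect_equal(length(unique(cl$cluster[n_per + 1:n_per])), 1)
  expect_true(cl$cluster[1] != cl$cluster[n_per + 1])
  # blocks align with time points here, so enrichment is strong
  expect_lt(cl$time_fisher_p, 1e-6)

  # labels independent of the gate give a large Fisher p
  set.seed(17)
  m2 <- matrix(pmax(rnorm(2 * n_per * 4, 5, 2), 0), 2 * n_per, 4,
               dimnames = dimnames(m))
  dct2 <- delta_ct_table(m2, wells, targets)
  cl2 <- circuit_cell_clustering(dct2, targets$target_id, gate_target = "T1")
  expect_gt(cl2$gate_fisher_p, 0.01)

  # all-zero targets are dropped with a warning
  m3 <- m; m3[, "T4"] <- 0
  dct3 <- delta_ct_table(m3, wells, targets)
  expect_warning(cl3 <- circuit_cell_clustering(dct3, targets$target_id,
                                                gate_target = "T1"), "T4")
  expect_equal(ncol(cl3$scaled), 3)
})
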