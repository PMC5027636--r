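test_that("normal-model fit recovers parameters and rejects gross misfit", {
  set.seed(3)
  ok <- 0L
  for (i in 1:40) {
    f <- fit_normal_model(rnorm(2000, 10, 1))
    if (abs(f$mu - 10) < 0.1 && !is.na(f$gof_p) && f$gof_p > 0.01) ok <- ok + 1L
  }
  expect_gte(ok / 40, 0.9)

  # constant vector is degenerate
  expect_true(fit_normal_model(rep(2, 20))$degenerate)

  # bimodal half-zeros data fails the chi-squared test decisively
  bim <- c(rep(0, 100), rnorm(100, 10, 0.5))
  expect_lt(fit_normal_model(bim)$gof_p, 0.01)
})

test_that("three-parameter fit recovers pi and the expressing component", {
  set.seed(4)
  pis <- numeric(100); mus <- numeric(100)
  for (i in 1:100) {
    x <- ifelse(runif(2000) < 0.6, rnorm(2000, 10, 1), 0)
    f <- fit_three_param_model(x, threshold = 0)
    pis[i] <- f$pi; mus[i] <- f$mu
  }
  expect_lt(abs(mean(pis) - 0.6), 0.01)      # bias of pi-hat
  expect_lt(abs(mean(mus) - 10), 0.1)
  expect_true(all(abs(pis - 0.6) < 0.03))

  # all detected: reduces to the two-parameter fit on the same values
  set.seed(5)
  x <- rnorm(500, 8, 1.2)
  f3 <- fit_three_param_model(x, threshold = 0)
  f2 <- fit_normal_model(x)
  expect_equal(f3$pi, 1)
  expect_equal(f3$mu, f2$mu)
  expect_equal(f3$sigma, f2$sigma)
  expect_equal(f3$gof_p, f2$gof_p)

  # all undetected: pi = 0, components undefined
  f0 <- fit_three_param_model(rep(0, 50), threshold = 0)
  expect_equal(f0$pi, 0)
  expect_true(is.na(f0$mu) && is.na(f0$sigma))
})

test_that("Fisher detection test matches exact enumeration and its rules", {
  # [[2,0],[0,2]] -> p = 1/3 by hypergeometric enumeration
  tab <- matrix(c(2, 0, 0, 2), 2)
  expect_equal(oracle_fisher_p(tab), 1 / 3, tolerance = 1e-12)
  expect_equal(fisher.test(tab)$p.value, 1 / 3, tolerance = 1e-12)

  # implementation vs oracle over all group splits up to 6 + 6
  set.seed(8)
  for (i in 1:60) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    va <- as.numeric(runif(na) < 0.5) * 3
    vb <- as.numeric(runif(nb) < 0.5) * 3
    res <- detection_proportion_test(va, vb, threshold = 0,
                                     min_undetected = 0)
    if (res$skipped) next
    tab <- matrix(c(sum(va > 0), sum(va == 0), sum(vb > 0), sum(vb == 0)), 2)
    expect_equal(res$p_value, oracle_fisher_p(tab), tolerance = 1e-9,
                 info = paste("case", i))
  }

  # eligibility: totals of undetected must exceed 10
  va <- c(rep(5, 20), rep(0, 3)); vb <- c(rep(5, 20), rep(0, 2))
  expect_true(detection_proportion_test(va, vb)$skipped)
  vb2 <- c(rep(5, 10), rep(0, 8))
  res <- detection_proportion_test(va, vb2)
  expect_false(res$skipped)
  expect_equal(res$direction, "DOWN")

  # equal detection proportions at large n give p near 1
  big_a <- rep(c(5, 0), 50); big_b <- rep(c(5, 0), 50)
  expect_gt(detection_proportion_test(big_a, big_b)$p_value, 0.9)
})

test_that("Mann-Whitney shift test matches exact enumeration and its rules", {
  # {1,2,3} vs {4,5,6}: exact two-sided p = 0.1
  r <- expression_shift_test(c(1, 2, 3), c(4, 5, 6), force = TRUE)
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  expect_equal(oracle_mwu_p(c(1, 2, 3), c(4, 5, 6)), 0.1, tolerance = 1e-12)
  expect_equal(r$direction, "UP")

  # implementation vs enumeration on random tie-free inputs up to 6 + 6
  set.seed(9)
  for (i in 1:60) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    pool <- sample(seq(0.5, 50, by = 0.5), na + nb)
    va <- pool[seq_len(na)]; vb <- pool[na + seq_len(nb)]
    res <- expression_shift_test(va, vb, force = TRUE)
    expect_equal(res$p_value, oracle_mwu_p(va, vb), tolerance = 1e-9,
                 info = paste("case", i))
  }

  # value-identical groups give p = 1
  expect_equal(expression_shift_test(c(1, 2, 3), c(1, 2, 3),
                                     force = TRUE)$p_value, 1)

  # eligibility: totals of detected must exceed 10
  expect_true(expression_shift_test(c(1, 2, 3, 0), c(4, 5, 6, 0))$skipped)
  expect_false(expression_shift_test(rep(1:6, 2), rep(2:7, 2))$skipped)
})

test_that("BH adjustment is monotone and matches the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  # manual step-up oracle: sort, p * m / rank, enforce monotonicity, cap
  step_up <- function(p) {
    m <- length(p); o <- order(p, decreasing = TRUE)
    pmin(1, cummin(p[o] * m / (m:1)))[order(o)]
  }
  set.seed(10)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))^2
    adj <- bh_adjust(p)
    expect_equal(adj, step_up(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_equal(order(adj[order(p)]), seq_along(p))  # order-preserving
    # re-adjusting never lowers values and keeps the ranking stable
    adj2 <- bh_adjust(adj)
    expect_true(all(adj2 >= adj))
    expect_equal(rank(adj2, ties.method = "min")[order(adj)],
                 sort(rank(adj2, ties.method = "min")))
  }
})

test_that("in-silico gating finds constructed dependence and counts tests", {
  # construct: target B detected exactly when A is detected
  set.seed(11)
  n <- 200
  a_det <- runif(n) < 0.5
  wells <- data.frame(well_id = sprintf("c%03d", 1:n), sample_type = "CELL",
                      time_point_hr = 0, n_cells_captured = 1,
                      dilution_quantity = NA_real_)
  targets <- data.frame(target_id = c("A_R", "B_R", "C_R"), analyte = "RNA",
                        gene = c("A", "B", "C"))
  m <- cbind(A_R = ifelse(a_det, rnorm(n, 8), 0),
             B_R = ifelse(a_det, rnorm(n, 6), 0),
             C_R = ifelse(runif(n) < 0.5, rnorm(n, 7), 0))
  m <- pmax(m, 0)
  rownames(m) <- wells$well_id
  dct <- delta_ct_table(m, wells, targets)
  res <- in_silico_gate_all(dct)
  # 3 gates x 2 responses x 2 test kinds attempted
  expect_equal(nrow(res), 12)
  ab <- res[res$gate_target == "A_R" & res$response_target == "B_R" &
            res$test == "FISHER_DETECTION", ]
  expect_lt(ab$p_adjusted, 0.01)
  ac <- res[res$gate_target == "A_R" & res$response_target == "C_R" &
            res$test == "FISHER_DETECTION", ]
  expect_gt(ac$p_adjusted, 0.05)

  # independent targets: adjusted discoveries are controlled on average
  set.seed(12)
  fp <- vapply(1:25, function(i) {
    m <- matrix(pmax(ifelse(runif(n * 3) < 0.5, rnorm(n * 3, 6), 0), 0), n)
    colnames(m) <- targets$target_id; rownames(m) <- wells$well_id
    r <- in_silico_gate_all(delta_ct_table(m, wells, targets))
    mean(r$p_adjusted < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(fp), 0.05 + 0.02)
})

test_that("group-wise differential testing detects shifted generators", {
  set.seed(13)
  n <- 100
  wells <- data.frame(well_id = sprintf("c%03d", 1:(2 * n)),
                      sample_type = "CELL",
                      time_point_hr = rep(c(0, 24), each = n),
                      n_cells_captured = 1, dilution_quantity = NA_real_)
  targets <- data.frame(target_id = c("A_R", "B_R"), analyte = "RNA",
                        gene = c("A", "B"))
  # A: detection 0.1 -> 0.9; B: level shift 6 -> 9 among expressing cells
  a <- c(ifelse(runif(n) < 0.1, rnorm(n, 6), 0),
         ifelse(runif(n) < 0.9, rnorm(n, 6), 0))
  b <- c(ifelse(runif(n) < 0.8, rnorm(n, 6, 1), 0),
         ifelse(runif(n) < 0.8, rnorm(n, 9, 1), 0))
  m <- pmax(cbind(A_R = a, B_R = b), 0)
  rownames(m) <- wells$well_id
  dct <- delta_ct_table(m, wells, targets)
  res <- de_between_groups(dct, wells$well_id[1:n], wells$well_id[n + 1:n])
  fa <- res[res$response_target == "A_R" & res$test == "FISHER_DETECTION", ]
  expect_lt(fa$p_adjusted, 1e-6)
  expect_equal(fa$direction, "UP")
  mb <- res[res$response_target == "B_R" & res$test == "MWU_LEVEL", ]
  expect_lt(mb$p_adjusted, 0.001)

  # value-identical groups: every eligible test returns p = 1
  m2 <- rbind(m[1:n, ], m[1:n, ])
  rownames(m2) <- wells$well_id
  dct2 <- delta_ct_table(m2, wells, targets)
  res2 <- de_between_groups(dct2, wells$well_id[1:n], wells$well_id[n + 1:n])
  expect_true(all(res2$p_value[!res2$skipped] >= 1 - 1e-9))
  expect_error(de_between_groups(dct, wells$well_id[1:n], wells$well_id[1:n]),
               "disjoint")
})
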