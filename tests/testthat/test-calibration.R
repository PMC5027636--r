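test_that("detection thresholds scale with background sd and alpha", {
  bg <- data.frame(target_id = c("A_P", "B_P"), bg_sd = c(0.5, 0))
  thr <- detection_threshold(bg, 0.01)
  expect_equal(thr$threshold_dct[1], qnorm(0.99) * 0.5, tolerance = 1e-12)
  expect_equal(thr$threshold_dct[1], 1.163, tolerance = 1e-3)
  expect_equal(thr$threshold_dct[2], 0)
  # alpha 0.5 -> z = 0 -> threshold 0
  expect_equal(detection_threshold(bg, 0.5)$threshold_dct, c(0, 0))
  expect_error(detection_threshold(bg, 0), "alpha")

  # strictly increasing in bg_sd, decreasing in alpha
  sds <- seq(0.1, 2, by = 0.1)
  t1 <- detection_threshold(data.frame(target_id = "x", bg_sd = sds), 0.01)
  expect_true(all(diff(t1$threshold_dct) > 0))
  alphas <- c(0.001, 0.01, 0.05, 0.2)
  t2 <- vapply(alphas, function(a)
    detection_threshold(data.frame(target_id = "x", bg_sd = 0.5),
                        a)$threshold_dct, numeric(1))
  expect_true(all(diff(t2) < 0))
})

test_that("detection calls are strict at the threshold", {
  expect_true(call_detection(1.5, 1.163))
  expect_false(call_detection(0, 0))
  expect_false(call_detection(1.163, 1.163))
  expect_equal(call_detection(c(0.2, 0.5, 0.8), 0.5), c(FALSE, FALSE, TRUE))
})

test_that("the penalized window search matches its worked example", {
  # means 1..5 then an off-line 0: dropping the last point buys R2 = 1 at a
  # 0.03 cost
  s <- make_series(2^(1:6), c(1, 2, 3, 4, 5, 0))
  f <- select_linear_range(s, range_cost = 0.03)
  expect_equal(c(f$lo_index, f$hi_index), c(1, 5))
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$score, 0.97, tolerance = 1e-12)
  expect_equal(f$n_removed, 1)
  o <- oracle_linear_range(s$quantities, rowMeans(s$dct), 0.03)
  expect_equal(c(o$lo, o$hi), c(1, 5))
  expect_lt(o$r2 - 1, 1e-12)
  # full window scores poorly (R2 about 0.02)
  full <- select_linear_range(s, range_cost = 0.03,
                              override = c(1, 6))
  expect_equal(full$r2, 0.0204, tolerance = 1e-3)

  # a perfectly linear series keeps the full window
  s2 <- make_series(2^(1:8), 1:8)
  f2 <- select_linear_range(s2)
  expect_equal(c(f2$lo_index, f2$hi_index, f2$n_removed), c(1, 8, 0))
  expect_equal(f2$r2, 1, tolerance = 1e-12)

  # zero-variance responses define R2 = 0
  s3 <- make_series(2^(1:4), rep(2, 4))
  expect_equal(select_linear_range(s3)$r2, 0)
  expect_error(select_linear_range(make_series(c(2, 4), c(1, 2))), ">= 3")
})

test_that("window search equals the brute-force oracle on random series", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(4:10, 1)
    q <- 2^seq(n, 1)
    means <- round(runif(n, 0, 8), 2)
    s <- make_series(q, means)
    f <- select_linear_range(s, range_cost = 0.03)
    o <- oracle_linear_range(q, means, 0.03)
    expect_equal(c(f$lo_index, f$hi_index), c(o$lo, o$hi),
                 info = paste("series", i))
    expect_equal(f$score, o$score, tolerance = 1e-10)
  }
})

test_that("limit of detection applies the 7-of-8 rule with scaling", {
  # detected counts [8, 8, 7, 5] at quantities [100, 50, 25, 12.5] -> LOD 25
  m <- rbind(rep(1, 8),
             rep(1, 8),
             c(rep(1, 7), 0),
             c(rep(1, 5), 0, 0, 0))
  s <- structure(list(target_id = "A_P", quantities = c(100, 50, 25, 12.5),
                      dct = m), class = "dilution_series")
  lod <- limit_of_detection(s, threshold = 0.5)
  expect_equal(lod$lod_quantity, 25)
  expect_equal(lod$detected_counts, c(8L, 8L, 7L, 5L))

  # no level reaches 7 -> undefined
  s2 <- structure(list(target_id = "A_P", quantities = c(100, 50),
                       dct = rbind(rep(c(1, 0), 4), rep(0, 8))),
                  class = "dilution_series")
  expect_true(is.na(limit_of_detection(s2, 0.5)$lod_quantity))

  # all levels at 8 -> smallest quantity
  s3 <- structure(list(target_id = "A_P", quantities = c(100, 50, 25),
                       dct = matrix(1, 3, 8)), class = "dilution_series")
  expect_equal(limit_of_detection(s3, 0.5)$lod_quantity, 25)

  # 4 replicates scale the rule to ceiling(7/8*4) = 4
  s4 <- structure(list(target_id = "A_P", quantities = c(100, 50),
                       dct = rbind(c(1, 1, 1, 1), c(1, 1, 1, 0))),
                  class = "dilution_series")
  expect_equal(limit_of_detection(s4, 0.5)$required, 4L)
  expect_equal(limit_of_detection(s4, 0.5)$lod_quantity, 100)
})

test_that("LOD is non-increasing as alpha rises", {
  d <- generate_dilution_series(quantities = 2^(7:0), slope = 0.8,
                                intercept = 0.3, noise_sd = 0.15, seed = 5)
  s <- dilution_series(dilution_delta_ct(d$ct), "SIM_P")
  bg <- data.frame(target_id = "SIM_P", bg_sd = 0.3)
  lods <- vapply(c(0.001, 0.01, 0.05, 0.2), function(a) {
    thr <- detection_threshold(bg, a)$threshold_dct
    lod <- limit_of_detection(s, thr)$lod_quantity
    if (is.na(lod)) Inf else lod
  }, numeric(1))
  expect_true(all(diff(lods) <= 0))
})

test_that("probe reliability classification separates the failure modes", {
  thr <- 0.5
  # clean linear series spanning the single-cell quantity, detected there
  good <- make_series(c(10.63, 5.31, 2.66, 1.33, 0.66, 0.33, 0.17, 0.04),
                      c(6, 5, 4, 3, 2, 1.2, 0.8, 0))
  fg <- select_linear_range(good)
  rg <- classify_probe_reliability(fg, good, thr)
  expect_true(rg$reliable)
  expect_equal(rg$failure_mode, "NONE")

  # flat at zero: no signal anywhere
  flat <- make_series(2^(3:-2), rep(0, 6))
  rf <- classify_probe_reliability(select_linear_range(flat), flat, thr)
  expect_false(rf$reliable)
  expect_equal(rf$failure_mode, "NO_SIGNAL")

  # constantly saturated: high signal, no slope
  sat <- make_series(2^(3:-2), rep(6, 6))
  rs <- classify_probe_reliability(select_linear_range(sat), sat, thr)
  expect_equal(rs$failure_mode, "SATURATED")

  # linear but only far above the single-cell level
  away <- make_series(c(400, 200, 100, 50), c(8, 7, 6, 5))
  ra <- classify_probe_reliability(select_linear_range(away), away, thr,
                                   single_cell_equivalents = 1.3)
  expect_false(ra$reliable)
  expect_equal(ra$failure_mode, "RANGE_EXCLUDES_SINGLE_CELL")
})

test_that("noisy synthetic windows are recovered and overrides are honoured", {
  # window recovery across seeds at small noise
  hits <- 0L
  for (seed in 1:200) {
    d <- generate_dilution_series(quantities = 2^(7:0), slope = 1,
                                  intercept = 2, noise_sd = 0.1,
                                  linear_lo = 2, linear_hi = 7, hook = TRUE,
                                  seed = seed)
    s <- dilution_series(dilution_delta_ct(d$ct), "SIM_P")
    f <- select_linear_range(s)
    if (f$lo_index == 2 && f$hi_index == 7) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)

  # an override forces the window and flags itself
  d <- generate_dilution_series(quantities = 2^(7:0), slope = 1,
                                intercept = 2, noise_sd = 0.05, seed = 3)
  s <- dilution_series(dilution_delta_ct(d$ct), "SIM_P")
  f <- select_linear_range(s, override = c(2, 6))
  expect_true(f$override)
  expect_equal(c(f$lo_index, f$hi_index), c(2, 6))
})

test_that("calibrate_assays summarizes a plate per target", {
  d <- generate_dilution_series(quantities = 2^(5:-2), slope = 1,
                                intercept = 3, noise_sd = 0.05, seed = 8)
  ddct <- dilution_delta_ct(d$ct)
  thr <- data.frame(target_id = "SIM_P", threshold_dct = 0.6, alpha = 0.01)
  res <- calibrate_assays(ddct, thr)
  expect_equal(nrow(res), 1)
  expect_true(res$reliable)
  expect_gt(res$slope, 0.9)
  expect_false(is.na(res$lod_quantity))
})
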