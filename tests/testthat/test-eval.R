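test_that("checkerboard2 bins follow the two-scale parity pattern", {
  spec <- grid_spec(0, 0, 8, 8, 1)
  # one point at each cell center of a 4x4 sub-lattice, factor (1,2)
  pts <- expand.grid(lon = cell_lons(spec)[1:4], lat = cell_lats(spec)[1:4])
  bins <- checkerboard2_partition(pts$lon, pts$lat, spec,
                                  aggregation_factors = c(1, 2))
  expect_setequal(unique(bins), 1:4)
  expect_equal(as.vector(table(bins)), rep(4L, 4))
  # all points in one cell share a bin
  one <- suppressWarnings(
    checkerboard2_partition(rep(0.5, 5), rep(0.5, 5), spec))
  expect_equal(length(unique(one)), 1)
  # independent parity oracle on random points
  set.seed(12)
  lon <- runif(200, 0, 8); lat <- runif(200, 0, 8)
  got <- suppressWarnings(
    checkerboard2_partition(lon, lat, spec, aggregation_factors = c(2, 2)))
  col0 <- floor(lon / 1); row0 <- floor((8 - lat) / 1)
  fine <- (floor(row0 / 2) + floor(col0 / 2)) %% 2
  coarse <- (floor(row0 / 4) + floor(col0 / 4)) %% 2
  expect_equal(got, as.integer(2 * coarse + fine + 1))
  expect_error(checkerboard2_partition(99, 99, spec), "outside")
})

test_that("AICc follows the small-sample formula and ranking rules", {
  expect_equal(aicc_score(-100, 2, 50), 204 + 12 / 47)
  expect_true(is.na(aicc_score(-10, 5, 6)))   # m <= k + 1 undefined
  # lnL equals a brute-force log-sum over explicitly normalized raw values
  ep <- make_env_pair(n_bg = 400, m = 60, seed = 3, truth = c(2, -1))
  fit <- maxent_fit(ep$p_env, ep$bg_env, classes = "LQ")
  ic <- model_aicc(fit, ep$p_env, ep$bg_env)
  raw_land <- predict(fit, ep$bg_env, type = "raw")
  raw_p <- predict(fit, ep$p_env, type = "raw")
  lnL_brute <- sum(log(raw_p / sum(raw_land)))
  expect_equal(ic$lnL, lnL_brute)
  expect_equal(ic$k, sum(fit$beta != 0))
  expect_true(ic$valid)
})

test_that("tuning selects delta-AICc zero and respects the candidate grid", {
  ep <- make_env_pair(n_bg = 400, m = 80, seed = 19, truth = c(2, -1.5))
  tr <- tune_sdm(ep$p_env, ep$bg_env, classes_grid = c("L", "LQ"),
                 multipliers = c(1, 2))
  expect_equal(nrow(tr$grid), 4)
  expect_equal(min(tr$grid$delta_AICc, na.rm = TRUE), 0)
  expect_equal(tr$selected$delta_AICc, 0)
  expect_gte(tr$selected$k, 1)
  # ranking invariant under a constant shift of lnL
  shifted <- tr$grid$AICc - 2 * 5   # adding c to lnL shifts AICc by -2c
  expect_equal(order(shifted), order(tr$grid$AICc))
})

test_that("fivefold partitions are balanced, seeded and exhaustive", {
  ep <- make_env_pair(n_bg = 300, m = 55, seed = 7, truth = c(2, 1))
  cv1 <- kfold_cv(ep$p_env, ep$bg_env, classes = "L", seed = 11, n_boot = 20)
  cv2 <- kfold_cv(ep$p_env, ep$bg_env, classes = "L", seed = 11, n_boot = 20)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(sum(cv1$folds$n_test), 55)
  expect_lte(diff(range(cv1$folds$n_test)), 1)
  # m = k folds: one test presence each
  ep5 <- make_env_pair(n_bg = 200, m = 5, seed = 8)
  cv5 <- kfold_cv(ep5$p_env, ep5$bg_env, classes = "L", k = 5, seed = 1,
                  n_boot = 10)
  expect_equal(cv5$folds$n_test, rep(1L, 5))
  expect_error(kfold_cv(ep5$p_env[1:3, ], ep5$bg_env, k = 5), "fewer")
})

test_that("partial ROC matches the brute-force trapezoid oracle", {
  set.seed(25)
  for (rep in 1:5) {
    test_pred <- runif(20)
    land_pred <- runif(200)
    pr <- partial_roc(test_pred, land_pred, n_boot = 2, seed = 1)
    expect_equal(pr$full_ratio, proc_oracle(test_pred, land_pred),
                 tolerance = 1e-10)
  }
})

test_that("partial ROC calibration: random near 1, perfect above 1", {
  set.seed(61)
  pr <- partial_roc(runif(300), runif(5000), n_boot = 500, seed = 2)
  expect_lt(abs(pr$proc_ratio - 1), 0.05)
  # test points at the landscape's highest suitability
  land <- runif(2000)
  top <- sort(land, decreasing = TRUE)[1:30]
  prt <- partial_roc(top, land, n_boot = 500, seed = 3)
  expect_gt(prt$proc_ratio, 1)
  expect_lt(prt$proc_p, 0.05)
  # anti-predictor scores below 1 (wide omission window so the restricted
  # region actually covers the anti-signal)
  bottom <- sort(land)[1:30]
  pra <- partial_roc(bottom, land, E = 0.5, n_boot = 500, seed = 4)
  expect_lt(pra$proc_ratio, 1)
  # degenerate constant landscape flagged
  expect_warning(bad <- partial_roc(runif(20), rep(0.5, 100)), "constant")
  expect_true(is.na(bad$proc_ratio))
  expect_error(partial_roc(runif(5), runif(100)), "at least 10")
})

test_that("jackknife gain identifies informative and redundant variables", {
  set.seed(44)
  n <- 1500; m <- 300
  bg <- cbind(sig = runif(n), noise = runif(n))
  idx <- sample(n, m, replace = TRUE, prob = exp(3 * bg[, "sig"]))
  p_env <- bg[idx, ]
  jk <- jackknife_gain(p_env, bg, classes = "L")
  expect_equal(jk$variable[which.max(jk$gain_alone)], "sig")
  full <- attr(jk, "full_gain")
  # no variable alone materially beats the full model
  expect_true(all(jk$gain_alone <= full + 1e-6))
  # duplicated informative variable: dropping either leaves the gain intact
  bg2 <- cbind(bg, sig2 = bg[, "sig"])
  jk2 <- jackknife_gain(bg2[idx, ], bg2, classes = "L")
  full2 <- attr(jk2, "full_gain")
  expect_equal(jk2$gain_without[jk2$variable == "sig"], full2,
               tolerance = 0.05)
})

test_that("percent contributions are non-negative, sum to 100, and track signal", {
  set.seed(50)
  n <- 1500; m <- 300
  bg <- cbind(bio6 = runif(n), bio12 = runif(n), bio15 = runif(n))
  idx <- sample(n, m, replace = TRUE, prob = exp(4 * bg[, "bio6"]))
  fit <- maxent_fit(bg[idx, ], bg, classes = "LQ")
  pc <- percent_contribution(fit)
  expect_true(all(pc >= 0))
  expect_equal(sum(pc), 100, tolerance = 0.1)
  expect_equal(names(which.max(pc)), "bio6")
  # single-variable model: all credit on that variable
  fit1 <- maxent_fit(bg[idx, "bio6", drop = FALSE],
                     bg[, "bio6", drop = FALSE], classes = "LQ")
  pc1 <- percent_contribution(fit1)
  expect_equal(unname(pc1["bio6"]), 100, tolerance = 1e-9)
  # zero-gain fit flagged
  null_fit <- maxent_fit(bg, bg, classes = "L")
  expect_warning(pcn <- percent_contribution(null_fit), "zero total gain")
  expect_true(all(is.na(pcn)))
})
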