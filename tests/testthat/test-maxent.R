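test_that("feature columns match straightforward re-implementations", {
  set.seed(6)
  env <- cbind(a = runif(50, -3, 7), b = runif(50, 100, 900))
  fs <- feature_spec(c("linear", "quadratic", "product", "threshold",
                       "hinge"), hinge_knots = 4, threshold_knots = 3)
  fs <- set_feature_ranges(fs, env)
  F <- build_features(env, fs)
  za <- (env[, "a"] - min(env[, "a"])) / diff(range(env[, "a"]))
  zb <- (env[, "b"] - min(env[, "b"])) / diff(range(env[, "b"]))
  expect_equal(unname(F[, "l:a"]), za)
  expect_equal(unname(F[, "q:b"]), zb^2)
  expect_equal(sum(startsWith(colnames(F), "p:")), 1)  # one pair
  expect_equal(unname(F[, "p:a*b"]), za * zb)
  # threshold: interior knots t/(K+1)
  expect_equal(unname(F[, "t:a:0.25"]), as.numeric(za >= 0.25))
  # hinge: forward max(0,(z-k)/(1-k)), reverse max(0,(k-z)/k)
  expect_equal(unname(F[, "hf:a:0.5"]), pmax(0, (za - 0.5) / 0.5))
  expect_equal(unname(F[, "hr:a:0.25"]), pmax(0, (0.25 - za) / 0.25))
  # training min -> 0, max -> 1 for the linear feature
  expect_equal(min(F[, "l:a"]), 0)
  expect_equal(max(F[, "l:a"]), 1)
  # constant variable: features dropped with a warning
  env2 <- cbind(env, c = 5)
  expect_warning(fs2 <- set_feature_ranges(feature_spec("linear"), env2),
                 "constant")
  expect_false("c" %in% colnames(fs2$ranges))
})

test_that("presences equal to the background give an all-zero model", {
  set.seed(10)
  bg <- cbind(v1 = runif(500), v2 = rnorm(500))
  fit <- maxent_fit(bg, bg, classes = "LQ", multiplier = 1)
  expect_true(all(abs(fit$beta) <= 1e-3))
  expect_true(fit$converged)
  expect_equal(fit$training_gain, 0, tolerance = 1e-9)
})

test_that("penalized objective matches the convex-optimizer oracle", {
  ep <- make_env_pair(n_bg = 1000, m = 100, seed = 33,
                      truth = c(1.5, -1))
  fit <- maxent_fit(ep$p_env, ep$bg_env, classes = "LQ", multiplier = 1)
  fs <- fit$features
  Fp <- build_features(ep$p_env, fs)
  Fb <- build_features(ep$bg_env, fs)
  oracle <- maxent_oracle_fit(Fp, Fb, fit$reg)
  mine <- maxent_objective(fit$beta, Fp, Fb, fit$reg)
  expect_equal(mine, oracle$objective, tolerance = 1e-3)
  expect_gte(mine, oracle$objective - 1e-3)  # ours is not worse
})

test_that("linear-truth coefficients are recovered on simulated data", {
  truth <- c(v1 = 1.2, v2 = -1.8)
  ep <- make_env_pair(n_bg = 10000, m = 2000, seed = 42, truth = truth)
  fit <- maxent_fit(ep$p_env, ep$bg_env, classes = "L", multiplier = 0.5)
  rng <- fit$features$ranges
  recovered <- fit$beta / (rng["max", ] - rng["min", ])
  expect_equal(unname(recovered), unname(truth), tolerance = 0.1)
})

test_that("the objective ascends monotonically across sweeps", {
  ep <- make_env_pair(n_bg = 800, m = 120, seed = 5, truth = c(2, 0.5))
  fit <- maxent_fit(ep$p_env, ep$bg_env, classes = "LQH", hinge_knots = 8)
  expect_true(all(diff(fit$obj_path) >= -1e-12))
})

test_that("stronger regularization never grows the coefficient mass", {
  ep <- make_env_pair(n_bg = 800, m = 150, seed = 17, truth = c(2.5, -1.5))
  mass <- vapply(c(0.5, 1, 2, 4), function(mult) {
    sum(abs(maxent_fit(ep$p_env, ep$bg_env, classes = "LQ",
                       multiplier = mult)$beta))
  }, numeric(1))
  expect_true(all(diff(mass) <= 1e-8))
})

test_that("raw predictions keep the training normalization and cloglog is bounded", {
  ep <- make_env_pair(n_bg = 600, m = 80, seed = 23, truth = c(1, 1))
  fit <- maxent_fit(ep$p_env, ep$bg_env, classes = "LQ")
  raw_bg <- predict(fit, ep$bg_env, type = "raw")
  expect_equal(sum(raw_bg), 1, tolerance = 1e-10)   # background mean 1/n
  p <- predict(fit, ep$bg_env)
  expect_true(all(p >= 0 & p <= 1))
  # cloglog definition from stored raw values
  expect_equal(p, 1 - exp(-exp(fit$entropy_H) * raw_bg), tolerance = 1e-12)
})

test_that("clamped projection beyond the training range hits the corner value", {
  ep <- make_env_pair(n_bg = 600, m = 80, seed = 29, truth = c(2, -1))
  fit <- maxent_fit(ep$p_env, ep$bg_env, classes = "LQ")
  rng <- fit$features$ranges
  beyond <- rbind(rng["max", ] + 10)
  corner <- rbind(rng["max", ])
  colnames(beyond) <- colnames(corner) <- colnames(rng)
  expect_equal(predict(fit, beyond), predict(fit, corner))
  # without clamping the two differ
  expect_false(isTRUE(all.equal(predict(fit, beyond, clamp = FALSE),
                                predict(fit, corner, clamp = FALSE))))
})

test_that("predictions are invariant to affine rescaling of variables", {
  ep <- make_env_pair(n_bg = 500, m = 60, seed = 31, truth = c(1.5, -2))
  fit1 <- maxent_fit(ep$p_env, ep$bg_env, classes = "LQ")
  scale_env <- function(E) {
    E2 <- E
    E2[, 1] <- 100 * E2[, 1] - 40     # degrees -> arbitrary units
    E2[, 2] <- 0.01 * E2[, 2] + 7
    E2
  }
  fit2 <- maxent_fit(scale_env(ep$p_env), scale_env(ep$bg_env),
                     classes = "LQ")
  expect_equal(predict(fit1, ep$bg_env), predict(fit2, scale_env(ep$bg_env)),
               tolerance = 1e-8)
})

test_that("minimum training presence equals the brute-force minimum", {
  ep <- make_env_pair(n_bg = 500, m = 70, seed = 37, truth = c(2, 1))
  fit <- maxent_fit(ep$p_env, ep$bg_env, classes = "LQ")
  thr <- min_training_presence(fit)
  preds <- predict(fit, ep$p_env)
  expect_equal(thr, min(preds))
  expect_equal(mean(preds < thr), 0)  # zero training omission
})

test_that("background sampling is uniform, seeded and exhaustive when small", {
  g <- make_test_grid(20, 25, seed = 3, na_frac = 0.2)
  layers <- list(bio6 = g)
  n_valid <- sum(!is.na(g$values))
  expect_warning(all_pts <- sample_background(layers, n = n_valid + 50,
                                              seed = 1), "taking all")
  expect_equal(nrow(all_pts), n_valid)
  b1 <- sample_background(layers, n = 100, seed = 7)
  b2 <- sample_background(layers, n = 100, seed = 7)
  expect_identical(b1, b2)
  expect_false(identical(b1, sample_background(layers, n = 100, seed = 8)))
  # sampled centers carry valid values
  expect_false(anyNA(extract_values(g, b1$longitude, b1$latitude)))
  # uniformity: chi-squared on cell occupancy over repeated seeds
  counts <- integer(length(g$values))
  for (s in 1:200) {
    cells <- attr(sample_background(layers, n = 50, seed = s), "cell")
    counts[cells] <- counts[cells] + 1L
  }
  counts <- counts[!is.na(as.vector(g$values))]
  p <- chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("model serialization round-trips predictions exactly", {
  ep <- make_env_pair(n_bg = 400, m = 60, seed = 41, truth = c(1, -1))
  fit <- maxent_fit(ep$p_env, ep$bg_env, classes = "LQH", hinge_knots = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_maxent_model(fit, path)
  back <- read_maxent_model(path)
  expect_identical(predict(back, ep$bg_env), predict(fit, ep$bg_env))
  expect_identical(back$beta, fit$beta)
})

test_that("fitting fails clearly on degenerate input", {
  expect_error(maxent_fit(matrix(1, 1, 1), matrix(runif(10)), "L"),
               "at least 2 presences")
  ep <- make_env_pair(n_bg = 100, m = 20, seed = 2)
  fit <- maxent_fit(ep$p_env, ep$bg_env, classes = "L")
  bad <- ep$bg_env[, 1, drop = FALSE]
  expect_error(predict(fit, bad), "v2")
})
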