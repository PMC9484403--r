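#' Checkerboard2 spatial partition
#'
#' Assigns points to one of four spatially structured bins by overlaying
#' two nested checkerboards on the raster geometry: a fine board whose
#' squares are `aggregation_factors[1]` cells wide and a coarse board
#' `aggregation_factors[1] * aggregation_factors[2]` cells wide. A point's
#' bin combines the parities of its fine and coarse squares, giving the
#' spatial block structure used to tune presence-background models.
#'
#' @param lon,lat Point coordinates.
#' @param spec The [grid_spec()] of the underlying raster.
#' @param aggregation_factors Two integers, fine and coarse aggregation
#'   (default `c(2, 2)`).
#' @return Integer bin labels in 1..4.
#' @export
checkerboard2_partition <- function(lon, lat, spec,
                                    aggregation_factors = c(2, 2)) {
  f1 <- aggregation_factors[1]
  f2 <- aggregation_factors[1] * aggregation_factors[2]
  rc <- cell_rowcol(spec, lon, lat)
  if (anyNA(rc)) stop("checkerboard2_partition: points outside the grid")
  i <- rc[, "row"] - 1L; j <- rc[, "col"] - 1L
  fine <- (i %/% f1 + j %/% f1) %% 2L
  coarse <- (i %/% f2 + j %/% f2) %% 2L
  bins <- as.integer(2L * coarse + fine + 1L)
  tab <- tabulate(bins, 4)
  if (any(tab == 0))
    warning("checkerboard2_partition: empty bin(s): ",
            paste(which(tab == 0), collapse = ", "))
  bins
}

#' Small-sample corrected AIC for a maxent model
#'
#' `aicc_score` applies the formula `2k - 2 lnL + 2k(k+1)/(m-k-1)`.
#' `model_aicc` computes `lnL` as the sum over presences of the log of the
#' raw prediction normalized to sum to 1 over the landscape, with
#' `k` = number of nonzero coefficients. Candidates with `m <= k + 1` are
#' flagged invalid (AICc undefined) and excluded from ranking.
#'
#' @param lnL Log-likelihood.
#' @param k Number of parameters (nonzero coefficients).
#' @param m Number of presences.
#' @return For `aicc_score`, the AICc value (`NA` when `m <= k + 1`).
#' @export
aicc_score <- function(lnL, k, m) {
  if (m <= k + 1) return(NA_real_)
  2 * k - 2 * lnL + 2 * k * (k + 1) / (m - k - 1)
}

#' @rdname aicc_score
#' @param model A `maxent_model`.
#' @param p_env Environmental matrix at the presences.
#' @param land_env Environmental matrix of the landscape cells over which
#'   the raw prediction is normalized.
#' @return For `model_aicc`, a list with `AICc`, `lnL`, `k`, `valid`.
#' @export
model_aicc <- function(model, p_env, land_env) {
  raw_land <- predict(model, as.matrix(land_env), type = "raw")
  raw_p <- predict(model, as.matrix(p_env), type = "raw")
  lnL <- sum(log(raw_p / sum(raw_land)))
  k <- sum(model$beta != 0)
  m <- nrow(p_env)
  list(AICc = aicc_score(lnL, k, m), lnL = lnL, k = k,
       valid = m > k + 1)
}

# model curve points for partial ROC: sensitivity and fractional predicted
# area at each threshold (thresholds ascending; both curves nonincreasing)
proc_ratio_once <- function(test_pred, s_land, thr, area, E) {
  s_test <- sort(test_pred)
  n_test <- length(s_test)
  sens <- (n_test - findInterval(thr - 1e-12, s_test)) / n_test
  keep <- sens >= 1 - E
  if (!any(keep)) return(NA_real_)
  x <- c(1, area[keep]); y <- c(1, sens[keep])   # threshold below min: (1,1)
  dx <- x[-length(x)] - x[-1]
  auc_model <- sum(dx * (y[-length(y)] + y[-1]) / 2)
  auc_rand <- sum(dx * (x[-length(x)] + x[-1]) / 2)
  if (auc_rand <= 0) return(NA_real_)
  auc_model / auc_rand
}

#' Partial ROC evaluation
#'
#' Computes the partial-ROC AUC ratio of Peterson-style niche-model
#' evaluation: the area under the sensitivity versus
#' fractional-predicted-area curve, restricted to the low-omission region
#' (omission at most `E`), divided by the area expected of a random
#' predictor over the same region. The ratio is 1 for random performance
#' and approaches 2 for perfect discrimination. Bootstrap resamples of the
#' test points give the mean ratio and a one-sided p-value (the proportion
#' of bootstrap ratios at or below 1).
#'
#' @param test_pred Suitability predictions at the test presences.
#' @param land_pred Suitability predictions over the landscape.
#' @param E Allowed omission (default 0.05).
#' @param n_boot Bootstrap iterations (default 1000).
#' @param boot_frac Fraction of test points resampled (with replacement)
#'   per iteration (default 0.5).
#' @param seed Integer seed.
#' @return List with `proc_ratio` (mean bootstrap ratio), `proc_p`,
#'   `ratios` (the bootstrap sample), and `full_ratio` (no resampling).
#' @export
partial_roc <- function(test_pred, land_pred, E = 0.05, n_boot = 1000,
                        boot_frac = 0.5, seed = NULL) {
  if (length(test_pred) < 10)
    stop("partial_roc: at least 10 test points required")
  if (length(unique(land_pred)) < 2) {
    warning("partial_roc: constant landscape predictions; ratio undefined")
    return(list(proc_ratio = NA_real_, proc_p = NA_real_,
                ratios = numeric(0), full_ratio = NA_real_))
  }
  s_land <- sort(land_pred)
  n_land <- length(s_land)
  thr <- unique(s_land)
  if (length(thr) > 1000)
    thr <- unique(stats::quantile(s_land, probs = seq(0, 1, length.out = 1000),
                                  names = FALSE, type = 1))
  thr <- sort(thr)
  area <- (n_land - findInterval(thr - 1e-12, s_land)) / n_land
  full_ratio <- proc_ratio_once(test_pred, s_land, thr, area, E)
  n_take <- max(1L, round(boot_frac * length(test_pred)))
  ratios <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      res <- sample(test_pred, n_take, replace = TRUE)
      proc_ratio_once(res, s_land, thr, area, E)
    }, numeric(1))
  })
  ratios <- ratios[!is.na(ratios)]
  list(proc_ratio = mean(ratios),
       proc_p = mean(ratios <= 1),
       ratios = ratios, full_ratio = full_ratio)
}

#' Fivefold cross-validation of a model configuration
#'
#' Randomly partitions the presences into `k` folds of near-equal size
#' (sizes differ by at most 1), refits the model on each set of `k - 1`
#' folds, and evaluates omission at the training minimum-presence
#' threshold and the partial-ROC ratio on the held-out fold.
#'
#' @param p_env Environmental matrix at the presences.
#' @param bg_env Environmental matrix at the background points (also used
#'   as the prediction landscape for held-out evaluation).
#' @param classes,multiplier Model configuration, as in [maxent_fit()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling the fold assignment.
#' @param n_boot Bootstrap iterations for the held-out partial ROC.
#' @param ... Passed to [maxent_fit()].
#' @return List with `folds` (per-fold data frame: `fold`, `n_test`,
#'   `omission`, `proc_ratio`) and the across-fold means.
#' @export
kfold_cv <- function(p_env, bg_env, classes = "LQH", multiplier = 1,
                     k = 5, seed = NULL, n_boot = 100, ...) {
  m <- nrow(p_env)
  if (m < k) stop("kfold_cv: fewer presences than folds")
  fold <- with_seed(seed, sample(rep(seq_len(k), length.out = m)))
  res <- lapply(seq_len(k), function(f) {
    tr <- p_env[fold != f, , drop = FALSE]
    te <- p_env[fold == f, , drop = FALSE]
    fit <- maxent_fit(tr, bg_env, classes = classes,
                      multiplier = multiplier, ...)
    thr <- min_training_presence(fit)
    pred_te <- predict(fit, te)
    omission <- mean(pred_te < thr)
    proc <- if (nrow(te) >= 10)
      partial_roc(pred_te, predict(fit, bg_env), n_boot = n_boot,
                  seed = seed)$proc_ratio
    else NA_real_
    data.frame(fold = f, n_test = nrow(te), omission = omission,
               proc_ratio = proc)
  })
  folds <- do.call(rbind, res)
  list(folds = folds, mean_omission = mean(folds$omission),
       mean_proc_ratio = mean(folds$proc_ratio, na.rm = TRUE))
}

#' Tune feature classes and regularization multiplier by AICc
#'
#' Fits every candidate configuration in the grid (by default the six
#' class combinations L, LQ, LQH, LQHP, LQPT, LQHPT crossed with
#' multipliers 0.5 to 4 in steps of 0.5), ranks candidates by AICc
#' computed over the landscape, and selects the candidate with
#' delta-AICc = 0. Optionally reports the mean test omission over the four
#' checkerboard2 spatial blocks for each candidate.
#'
#' @param p_env,bg_env Presence and background environmental matrices.
#' @param land_env Landscape environmental matrix for the AICc likelihood
#'   normalization (defaults to `bg_env`).
#' @param classes_grid Character vector of class-combination abbreviations.
#' @param multipliers Numeric vector of regularization multipliers.
#' @param partition_bins Optional integer bins (1..4) for the presences,
#'   e.g. from [checkerboard2_partition()]; when supplied, each
#'   candidate's mean spatial-block omission is reported.
#' @param ... Passed to [maxent_fit()].
#' @return An object of class `tuning_result`: data frame `grid` with
#'   `classes`, `multiplier`, `k`, `lnL`, `AICc`, `delta_AICc`,
#'   `mean_omission`, `valid`; plus `selected` (row of the best
#'   candidate) and `best` (its refitted `maxent_model`).
#' @export
tune_sdm <- function(p_env, bg_env, land_env = bg_env,
                     classes_grid = c("L", "LQ", "LQH", "LQHP", "LQPT",
                                      "LQHPT"),
                     multipliers = seq(0.5, 4, by = 0.5),
                     partition_bins = NULL, ...) {
  cand <- expand.grid(classes = classes_grid, multiplier = multipliers,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    cl <- cand$classes[i]; mu <- cand$multiplier[i]
    fit <- suppressWarnings(
      maxent_fit(p_env, bg_env, classes = cl, multiplier = mu, ...))
    ic <- model_aicc(fit, p_env, land_env)
    om <- NA_real_
    if (!is.null(partition_bins)) {
      oms <- vapply(sort(unique(partition_bins)), function(b) {
        tr <- p_env[partition_bins != b, , drop = FALSE]
        te <- p_env[partition_bins == b, , drop = FALSE]
        if (nrow(tr) < 2 || nrow(te) < 1) return(NA_real_)
        f <- suppressWarnings(
          maxent_fit(tr, bg_env, classes = cl, multiplier = mu, ...))
        mean(predict(f, te) < min_training_presence(f))
      }, numeric(1))
      om <- mean(oms, na.rm = TRUE)
    }
    data.frame(classes = cl, multiplier = mu, k = ic$k, lnL = ic$lnL,
               AICc = ic$AICc, mean_omission = om, valid = ic$valid)
  })
  grid <- do.call(rbind, rows)
  comparable <- grid$valid & !is.na(grid$AICc)
  if (!any(comparable)) stop("tune_sdm: no comparable candidate (AICc ",
                             "undefined for all)")
  best_aicc <- min(grid$AICc[comparable])
  grid$delta_AICc <- grid$AICc - best_aicc
  grid$delta_AICc[!comparable] <- NA_real_
  sel <- which(comparable & grid$delta_AICc == 0)[1]
  best <- suppressWarnings(
    maxent_fit(p_env, bg_env, classes = grid$classes[sel],
               multiplier = grid$multiplier[sel], ...))
  structure(list(grid = grid, selected = grid[sel, ], best = best),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("tuning_result: %d candidates; selected %s @ multiplier %g (AICc %.2f)\n",
              nrow(x$grid), x$selected$classes, x$selected$multiplier,
              x$selected$AICc))
  invisible(x)
}

# variables underlying each feature, parsed from feature names
feature_var_list <- function(feature_names) {
  lapply(feature_names, function(nm) {
    body <- sub("^[a-z]+:", "", nm)
    body <- sub(":[-0-9.e]+$", "", body)
    strsplit(body, "*", fixed = TRUE)[[1]]
  })
}

#' Jackknife of regularized training gain
#'
#' Measures each variable's importance by refitting the model with only
#' that variable's features (`gain_alone`) and with every variable except
#' it (`gain_without`). Gain is the unpenalized part of the fitted
#' objective relative to the uniform null model (which has gain 0).
#'
#' @param p_env,bg_env Presence and background environmental matrices
#'   (at least 2 variables).
#' @param classes,multiplier Model configuration.
#' @param ... Passed to [maxent_fit()].
#' @return Data frame `variable`, `gain_alone`, `gain_without`, with
#'   attribute `full_gain`.
#' @export
jackknife_gain <- function(p_env, bg_env, classes = "LQH", multiplier = 1,
                           ...) {
  vars <- colnames(p_env)
  if (length(vars) < 2) stop("jackknife_gain: at least 2 variables needed")
  gain_of <- function(cols) {
    f <- try(suppressWarnings(
      maxent_fit(p_env[, cols, drop = FALSE], bg_env[, cols, drop = FALSE],
                 classes = classes, multiplier = multiplier, ...)),
      silent = TRUE)
    if (inherits(f, "try-error")) NA_real_ else f$training_gain
  }
  full <- gain_of(vars)
  out <- data.frame(
    variable = vars,
    gain_alone = vapply(vars, function(v) gain_of(v), numeric(1)),
    gain_without = vapply(vars, function(v) gain_of(setdiff(vars, v)),
                          numeric(1)),
    row.names = NULL)
  attr(out, "full_gain") <- full
  out
}

#' Percent contribution of each variable
#'
#' Credits every accepted optimizer step's objective improvement to the
#' variable(s) underlying the stepped feature (product features split
#' their credit equally between the two variables) and normalizes the
#' totals to percentages summing to 100.
#'
#' @param model A `maxent_model` (the fit records the per-feature credit).
#' @return Named numeric vector of percentages, one per model variable.
#' @export
percent_contribution <- function(model) {
  credit <- model$gain_credit
  vars <- model$vars
  per_var <- stats::setNames(rep(0, length(vars)), vars)
  vl <- feature_var_list(names(credit))
  for (i in seq_along(credit)) {
    share <- credit[i] / length(vl[[i]])
    for (v in vl[[i]]) per_var[v] <- per_var[v] + share
  }
  total <- sum(per_var)
  if (total <= 0) {
    warning("percent_contribution: zero total gain; contributions undefined")
    return(per_var * NA_real_)
  }
  100 * per_var / total
}
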