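# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Environmental values of layers at points or over the landscape
#'
#' @param layers Named list of [raster_grid()]s (one per variable).
#' @param lon,lat Point coordinates; if omitted, values for every jointly
#'   valid cell of the landscape are returned.
#' @return Numeric matrix, one named column per layer. For the landscape
#'   form, the attribute `cell` holds the linear cell index of each row.
#' @export
env_at <- function(layers, lon = NULL, lat = NULL) {
  if (is.null(lon)) {
    M <- do.call(cbind, lapply(layers, function(g) as.vector(g$values)))
    colnames(M) <- names(layers)
    ok <- rowSums(is.na(M)) == 0
    out <- M[ok, , drop = FALSE]
    attr(out, "cell") <- which(ok)
    return(out)
  }
  M <- do.call(cbind, lapply(layers, extract_values, lon = lon, lat = lat))
  colnames(M) <- names(layers)
  M
}

#' Sample background points
#'
#' Draws a uniform sample, without replacement, of the centers of the
#' jointly valid cells of the environmental layers. The same background
#' set is intended to be reused across species.
#'
#' @param layers Named list of [raster_grid()]s.
#' @param n Number of background points (default 10000). If fewer valid
#'   cells exist, all are taken with a warning.
#' @param seed Integer seed for reproducibility.
#' @return Data frame `longitude`, `latitude` with attribute `cell`.
#' @export
sample_background <- function(layers, n = 10000, seed = NULL) {
  spec <- layers[[1]]$spec
  M <- do.call(cbind, lapply(layers, function(g) as.vector(g$values)))
  valid <- which(rowSums(is.na(M)) == 0)
  if (!length(valid)) stop("sample_background: no valid cells")
  if (length(valid) <= n) {
    if (length(valid) < n)
      warning("sample_background: only ", length(valid),
              " valid cells; taking all")
    cells <- valid
  } else {
    cells <- with_seed(seed, sort(sample(valid, n)))
  }
  row <- (cells - 1) %% spec$n_rows + 1
  col <- (cells - 1) %/% spec$n_rows + 1
  out <- data.frame(longitude = cell_lons(spec)[col],
                    latitude = cell_lats(spec)[row])
  attr(out, "cell") <- cells
  out
}

#' Fit a maximum-entropy species distribution model
#'
#' Maximizes the L1-penalized presence/background log-likelihood
#' \deqn{L(\beta) = \frac1m\sum_{presences}\eta(x) -
#'   \log\Big(\frac1n\sum_{background} e^{\eta(z)}\Big) -
#'   \sum_j \lambda_j |\beta_j|}
#' over the feature expansion of the environmental variables, by cyclic
#' coordinate ascent with per-coordinate Newton steps, soft-thresholding
#' for the L1 term, and step halving to guarantee monotone ascent. The
#' per-feature penalty is `multiplier x class default x sd/sqrt(m)` (the
#' published MaxEnt default schedule interpolated by presence count).
#' The objective is concave, so the fit is deterministic given its inputs.
#'
#' @param p_env Numeric matrix of environmental values at the `m` presence
#'   points (named columns = variables).
#' @param bg_env Numeric matrix of values at the `n` background points.
#' @param classes Feature classes, as a character vector or an
#'   abbreviation such as `"LQH"` (L = linear, Q = quadratic, H = hinge,
#'   P = product, T = threshold).
#' @param multiplier Regularization multiplier (default 1; the tuning grid
#'   of [tune_sdm()] spans 0.5 to 4).
#' @param hinge_knots,threshold_knots Knots per variable (default 50).
#' @param tol Convergence tolerance on the objective change per full sweep.
#' @param max_iter Maximum number of sweeps.
#' @return An object of class `maxent_model`: coefficients `beta`, the
#'   feature spec with training ranges, penalties `reg`, normalizer
#'   `alpha` (log-sum of exp(eta) over the training background, so raw
#'   values sum to 1 there), `entropy_H` of the background raw
#'   distribution, objective path, and a per-feature gain trace used for
#'   percent-contribution estimates.
#' @export
maxent_fit <- function(p_env, bg_env, classes = "LQH", multiplier = 1,
                       hinge_knots = 50, threshold_knots = 50,
                       tol = 1e-6, max_iter = 500) {
  if (length(classes) == 1 && grepl("^[LQHPT]+$", classes))
    classes <- expand_classes(classes)
  p_env <- as.matrix(p_env); bg_env <- as.matrix(bg_env)
  m <- nrow(p_env); n <- nrow(bg_env)
  if (m < 2) stop("maxent_fit: at least 2 presences required")
  fspec <- feature_spec(classes, hinge_knots, threshold_knots)
  fspec <- set_feature_ranges(fspec, rbind(p_env, bg_env))
  Fp <- build_features(p_env, fspec)
  Fb <- build_features(bg_env, fspec)
  p <- ncol(Fb)
  reg <- feature_penalties(Fp, multiplier, m)

  pbar <- colMeans(Fp)
  beta <- stats::setNames(rep(0, p), colnames(Fb))
  w <- rep(1, n)                 # exp(eta) over background, unnormalized
  lme <- 0                       # log(mean(exp(eta)))
  lp <- 0                        # sum(beta * pbar)
  obj <- 0                       # penalized objective; starts at null = 0
  obj_path <- numeric(0)
  gain_credit <- stats::setNames(rep(0, p), colnames(Fb))
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    sw <- sum(w)
    Eq_all <- as.vector(crossprod(Fb, w)) / sw
    active <- which(beta != 0 | abs(pbar - Eq_all) > reg + 1e-12)
    for (j in active) {
      pb <- pbar[[j]]
      bj <- beta[[j]]
      f <- Fb[, j]
      sw <- sum(w)
      wf <- w * f
      Ef <- sum(wf) / sw
      Ef2 <- sum(wf * f) / sw
      h <- max(Ef2 - Ef^2, 1e-10)
      g <- pb - Ef
      z <- bj + g / h
      b_new <- soft_threshold(z, reg[[j]] / h)
      delta <- b_new - bj
      if (abs(delta) < 1e-14) next
      if (abs(delta) > 10) delta <- sign(delta) * 10
      accepted <- FALSE
      for (half in 1:30) {
        d_lme <- log(sum(w * exp(delta * f)) / sw)
        d_obj <- pb * delta - d_lme -
          reg[[j]] * (abs(bj + delta) - abs(bj))
        if (d_obj >= -1e-12) { accepted <- TRUE; break }
        delta <- delta / 2
      }
      if (!accepted || abs(delta) < 1e-14) next
      beta[j] <- bj + delta
      if (abs(beta[[j]]) < 1e-14) beta[j] <- 0
      w <- w * exp(delta * f)
      lme <- lme + d_lme
      lp <- lp + pb * delta
      obj <- obj + d_obj
      gain_credit[j] <- gain_credit[j] + max(d_obj, 0)
      if (max(w) > 1e100 || max(w) < 1e-100) {
        s <- max(w); w <- w / s
      }
    }
    obj_path <- c(obj_path, obj)
    if (iter > 1 &&
        obj_path[iter] - obj_path[iter - 1] < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("maxent_fit: not converged in ", max_iter, " sweeps ",
            "(last objective change ",
        signif(diff(utils::tail(obj_path, 2)), 3), ")")

  eta_bg <- as.vector(Fb %*% beta)
  lse <- max(eta_bg) + log(sum(exp(eta_bg - max(eta_bg))))
  raw_bg <- exp(eta_bg - lse)          # sums to 1 over background
  H <- -sum(ifelse(raw_bg > 0, raw_bg * log(raw_bg), 0))

  structure(list(
    beta = beta, features = fspec, reg = reg, multiplier = multiplier,
    alpha = lse, entropy_H = H,
    m = m, n = n, vars = colnames(fspec$ranges),
    training_gain = lp - lme,          # unpenalized gain over the null
    objective = obj, obj_path = obj_path, converged = converged,
    gain_credit = gain_credit, pbar = pbar,
    p_env = p_env),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("maxent_model: %d variables, %d/%d nonzero features, ",
              length(x$vars), sum(x$beta != 0), length(x$beta)))
  cat(sprintf("multiplier %g\n", x$multiplier))
  cat(sprintf("  m = %d presences, n = %d background, training gain %.4f, H %.4f\n",
              x$m, x$n, x$training_gain, x$entropy_H))
  invisible(x)
}

# eta/raw/cloglog at arbitrary environmental values
maxent_eval <- function(model, env, clamp = TRUE) {
  missing <- setdiff(model$vars, colnames(env))
  if (length(missing))
    stop("predict: environment is missing variable(s): ",
         paste(missing, collapse = ", "))
  F <- build_features(env, model$features, clamp = clamp)
  eta <- as.vector(F %*% model$beta)
  raw <- exp(eta - model$alpha)
  cloglog <- 1 - exp(-exp(model$entropy_H) * raw)
  cloglog <- pmin(pmax(cloglog, 0), 1)
  list(eta = eta, raw = raw, cloglog = cloglog)
}

#' Project a fitted model onto environmental layers
#'
#' Evaluates the model at every jointly valid cell. With `clamp = TRUE`
#' (the default) each variable is clamped to its training range before the
#' feature expansion, so projections onto novel climates never extrapolate
#' feature values. The raw exponential density keeps the training
#' normalization (it sums to 1 over the training background), and
#' suitability is the cloglog transform `1 - exp(-exp(H) * raw)`,
#' truncated into [0, 1].
#'
#' @param object A `maxent_model`.
#' @param layers Named list of [raster_grid()]s containing every model
#'   variable, or a numeric matrix of environmental values.
#' @param clamp Clamp variables to their training ranges.
#' @param type `"cloglog"` (default) or `"raw"`.
#' @param ... Unused.
#' @return For layer input, a `suitability_grid` (a [raster_grid()] with
#'   the model's window attached); for matrix input, a numeric vector.
#' @export
predict.maxent_model <- function(object, layers, clamp = TRUE,
                                 type = c("cloglog", "raw"), ...) {
  type <- match.arg(type)
  if (is.matrix(layers) || is.data.frame(layers)) {
    ev <- maxent_eval(object, as.matrix(layers), clamp = clamp)
    return(ev[[type]])
  }
  env <- env_at(layers)
  ev <- maxent_eval(object, env, clamp = clamp)
  spec <- layers[[1]]$spec
  vals <- rep(NA_real_, spec$n_rows * spec$n_cols)
  vals[attr(env, "cell")] <- ev[[type]]
  g <- raster_grid(matrix(vals, spec$n_rows, spec$n_cols), spec)
  structure(list(values = g$values, spec = spec,
                 window = attr(layers, "window"), type = type),
            class = c("suitability_grid", "raster_grid"))
}

#' Minimum training presence threshold
#'
#' The smallest predicted cloglog suitability over the training presences:
#' binarizing the map at this threshold gives zero training omission by
#' construction.
#'
#' @param model A `maxent_model`.
#' @param p_env Environmental matrix of the training presences; defaults
#'   to the matrix stored in the model.
#' @return The threshold, a single number in [0, 1].
#' @export
min_training_presence <- function(model, p_env = model$p_env) {
  min(maxent_eval(model, as.matrix(p_env), clamp = TRUE)$cloglog)
}

#' Serialize a fitted model to structured plain text
#'
#' Writes/reads the complete model state (feature spec, ranges,
#' coefficients, penalties, normalizer, entropy) as JSON so projections
#' are reproducible bit-for-bit.
#'
#' @param model A `maxent_model`.
#' @param path File path.
#' @export
write_maxent_model <- function(model, path) {
  x <- unclass(model)
  x$p_env <- NULL; x$obj_path <- NULL
  # named vectors must go out as JSON objects, not bare arrays
  for (f in c("beta", "reg", "gain_credit", "pbar"))
    x[[f]] <- as.list(x[[f]])
  x$features <- list(classes = x$features$classes,
                     hinge_knots = x$features$hinge_knots,
                     threshold_knots = x$features$threshold_knots,
                     ranges = as.data.frame(x$features$ranges),
                     dropped_vars = x$features$dropped_vars)
  jsonlite::write_json(x, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_maxent_model
#' @export
read_maxent_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rng <- as.matrix(x$features$ranges)
  rownames(rng) <- c("min", "max")
  fs <- feature_spec(x$features$classes, x$features$hinge_knots,
                     x$features$threshold_knots, ranges = rng)
  fs$dropped_vars <- x$features$dropped_vars
  x$features <- fs
  x$beta <- unlist(x$beta)
  x$reg <- unlist(x$reg)
  x$gain_credit <- unlist(x$gain_credit)
  x$pbar <- unlist(x$pbar)
  class(x) <- "maxent_model"
  x
}
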