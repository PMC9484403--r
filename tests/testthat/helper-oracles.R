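# Independent oracles, deliberately written as plain scalar code so they
# share no logic with the package implementations they check.

# the 19 bioclimatic variables from one cell's 12-month vectors, by direct
# scalar arithmetic with explicit quarter loops
bioclim_oracle <- function(tmin, tmax, prec) {
  tmean <- (tmax + tmin) / 2
  out <- numeric(19)
  out[1] <- mean(tmean)
  out[2] <- mean(tmax - tmin)
  out[4] <- 100 * sd(tmean)
  out[5] <- max(tmax)
  out[6] <- min(tmin)
  out[7] <- out[5] - out[6]
  out[3] <- if (out[7] == 0) NA_real_ else 100 * out[2] / out[7]
  out[12] <- sum(prec)
  out[13] <- max(prec)
  out[14] <- min(prec)
  out[15] <- 100 * sd(prec) / (1 + mean(prec))
  qp <- qt <- numeric(12)
  for (q in 1:12) {
    months <- ((q - 1):(q + 1)) %% 12 + 1
    qp[q] <- sum(prec[months])
    qt[q] <- mean(tmean[months])
  }
  wet <- which.max(qp); dry <- which.min(qp)
  warm <- which.max(qt); cold <- which.min(qt)
  out[8] <- qt[wet];  out[9] <- qt[dry]
  out[10] <- qt[warm]; out[11] <- qt[cold]
  out[16] <- qp[wet]; out[17] <- qp[dry]
  out[18] <- qp[warm]; out[19] <- qp[cold]
  out
}

# penalized maxent objective (to be maximized) for a coefficient vector
maxent_objective <- function(beta, Fp, Fb, reg) {
  eta_b <- as.vector(Fb %*% beta)
  mean(as.vector(Fp %*% beta)) - log(mean(exp(eta_b))) - sum(reg * abs(beta))
}

# generic convex-optimizer oracle: maximizes the same objective via
# L-BFGS-B on the positive/negative split beta = bp - bn, bp, bn >= 0,
# which turns the L1 term into a smooth linear penalty
maxent_oracle_fit <- function(Fp, Fb, reg) {
  p <- ncol(Fb)
  pbar <- colMeans(Fp)
  fn <- function(par) {
    beta <- par[1:p] - par[p + 1:p]
    -(sum(pbar * beta) - log(mean(exp(as.vector(Fb %*% beta)))) -
        sum(reg * (par[1:p] + par[p + 1:p])))
  }
  gr <- function(par) {
    beta <- par[1:p] - par[p + 1:p]
    w <- exp(as.vector(Fb %*% beta))
    Eq <- as.vector(crossprod(Fb, w)) / sum(w)
    g <- -(pbar - Eq)
    c(g + reg, -g + reg)
  }
  res <- optim(rep(0, 2 * p), fn, gr, method = "L-BFGS-B",
               lower = 0, control = list(maxit = 2000, factr = 1e4))
  list(beta = res$par[1:p] - res$par[p + 1:p], objective = -res$value)
}

# brute-force partial-AUC ratio: explicit loops over every unique
# landscape threshold, trapezoid integration of sensitivity vs fractional
# area over the low-omission region, anchored at (1, 1)
proc_oracle <- function(test_pred, land_pred, E = 0.05) {
  thr <- sort(unique(land_pred))
  pts <- data.frame(x = numeric(0), y = numeric(0))
  for (t in thr) {
    x <- mean(land_pred >= t)
    y <- mean(test_pred >= t)
    if (y >= 1 - E) pts <- rbind(pts, data.frame(x = x, y = y))
  }
  pts <- rbind(data.frame(x = 1, y = 1), pts)
  pts <- pts[order(-pts$x), ]
  auc_m <- 0; auc_r <- 0
  for (i in seq_len(nrow(pts) - 1)) {
    dx <- pts$x[i] - pts$x[i + 1]
    auc_m <- auc_m + dx * (pts$y[i] + pts$y[i + 1]) / 2
    auc_r <- auc_r + dx * (pts$x[i] + pts$x[i + 1]) / 2
  }
  auc_m / auc_r
}

# small random raster on a simple geometry
make_test_grid <- function(n_rows = 10, n_cols = 10, seed = 1,
                           na_frac = 0) {
  set.seed(seed)
  v <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  if (na_frac > 0)
    v[sample(length(v), round(na_frac * length(v)))] <- NA
  raster_grid(v, grid_spec(0, 0, n_cols, n_rows, 1))
}

# monthly normals with given constant or per-month values on a tiny grid
make_normals <- function(tmin, tmax, prec, n_rows = 2, n_cols = 2,
                         window = c(2013, 2018)) {
  g <- grid_spec(0, 0, n_cols, n_rows, 1)
  rep12 <- function(x) if (length(x) == 1) rep(x, 12) else x
  tmin <- rep12(tmin); tmax <- rep12(tmax); prec <- rep12(prec)
  climate_normals(
    tmin = lapply(tmin, function(x) raster_grid(matrix(x, n_rows, n_cols), g)),
    tmax = lapply(tmax, function(x) raster_grid(matrix(x, n_rows, n_cols), g)),
    prec = lapply(prec, function(x) raster_grid(matrix(x, n_rows, n_cols), g)),
    window = window)
}

# random environmental matrices for model fitting tests
make_env_pair <- function(n_bg = 1000, m = 100, n_var = 2, seed = 1,
                          truth = NULL) {
  set.seed(seed)
  bg <- matrix(runif(n_bg * n_var), n_bg, n_var,
               dimnames = list(NULL, paste0("v", seq_len(n_var))))
  if (is.null(truth)) {
    idx <- sample(n_bg, m, replace = TRUE)
  } else {
    eta <- as.vector(bg %*% truth)
    idx <- sample(n_bg, m, replace = TRUE, prob = exp(eta))
  }
  list(p_env = bg[idx, , drop = FALSE], bg_env = bg)
}
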