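#' Monthly climate normals for a time window
#'
#' Twelve monthly grids each of minimum temperature (deg C), maximum
#' temperature (deg C) and precipitation (mm), averaged over a named
#' multi-year window.
#'
#' @param tmin,tmax,prec Lists of 12 [raster_grid()]s (January..December),
#'   all on one grid geometry.
#' @param window Integer vector `c(start_year, end_year)`.
#' @return An object of class `climate_normals`.
#' @export
climate_normals <- function(tmin, tmax, prec, window) {
  stopifnot(length(tmin) == 12, length(tmax) == 12, length(prec) == 12)
  spec <- tmin[[1]]$spec
  for (g in c(tmin, tmax, prec))
    if (!same_spec(g$spec, spec))
      stop("climate_normals: all 36 grids must share one grid_spec")
  for (m in 1:12) {
    d <- tmax[[m]]$values - tmin[[m]]$values
    if (any(d < -1e-9, na.rm = TRUE))
      stop("climate_normals: tmax < tmin in month ", m)
    if (any(prec[[m]]$values < 0, na.rm = TRUE))
      stop("climate_normals: negative precipitation in month ", m)
  }
  structure(list(tmin = tmin, tmax = tmax, prec = prec,
                 window = as.integer(window), spec = spec),
            class = "climate_normals")
}

#' Average a per-year monthly climate series over a window
#'
#' For each calendar month, takes the cell-wise arithmetic mean of that
#' month's grid across every year of the window (e.g. the six Januaries of
#' a six-year window).
#'
#' @param series Named list, one element per year (names are the years);
#'   each element a list with `tmin`, `tmax`, `prec`, each a list of 12
#'   [raster_grid()]s.
#' @param window `c(start_year, end_year)`, inclusive.
#' @return A [climate_normals()] for the window.
#' @export
window_average <- function(series, window) {
  years <- seq(window[1], window[2])
  missing <- setdiff(as.character(years), names(series))
  if (length(missing))
    stop("window_average: series is missing years: ",
         paste(missing, collapse = ", "))
  avg_month <- function(var, m) {
    grids <- lapply(as.character(years), function(y) {
      g <- series[[y]][[var]][[m]]
      if (is.null(g)) stop("window_average: missing ", var,
                           " month ", m, " in year ", y)
      g
    })
    acc <- grids[[1]]$values
    for (g in grids[-1]) acc <- acc + g$values
    raster_grid(acc / length(grids), grids[[1]]$spec)
  }
  climate_normals(
    tmin = lapply(1:12, function(m) avg_month("tmin", m)),
    tmax = lapply(1:12, function(m) avg_month("tmax", m)),
    prec = lapply(1:12, function(m) avg_month("prec", m)),
    window = window)
}

#' Stack of the 19 bioclimatic variables
#'
#' @param bio Named list `bio1`..`bio19` of [raster_grid()]s.
#' @param window `c(start_year, end_year)` the stack summarizes.
#' @return An object of class `bioclim_stack`.
#' @export
bioclim_stack <- function(bio, window) {
  stopifnot(length(bio) == 19)
  names(bio) <- paste0("bio", 1:19)
  structure(list(bio = bio, window = as.integer(window),
                 spec = bio[[1]]$spec),
            class = "bioclim_stack")
}

#' @export
print.bioclim_stack <- function(x, ...) {
  cat(sprintf("bioclim_stack (window %d-%d)\n", x$window[1], x$window[2]))
  print(x$spec)
  invisible(x)
}

# month-of-quarter indicator matrix: column q = quarter starting in month q,
# three consecutive months with December -> January wrap
quarter_matrix <- function() {
  Q <- matrix(0, 12, 12)
  for (q in 1:12) Q[(q + 0:2 - 1) %% 12 + 1, q] <- 1
  Q
}

#' Compute the 19 bioclimatic variables from monthly normals
#'
#' Standard definitions on the 12 monthly values of each cell, with
#' `tmean_m = (tmax_m + tmin_m)/2`:
#' BIO1 mean of tmean; BIO2 mean diurnal range, mean of (tmax - tmin);
#' BIO3 isothermality, 100 * BIO2 / BIO7; BIO4 temperature seasonality,
#' 100 * sd(tmean) (sample sd, n-1 denominator); BIO5 max tmax; BIO6 min
#' tmin; BIO7 annual range, BIO5 - BIO6; BIO12 annual precipitation;
#' BIO13/BIO14 wettest/driest month; BIO15 precipitation seasonality,
#' 100 * sd(prec) / (1 + mean(prec)). Quarters are three consecutive
#' months with December-to-January wrap; ties are broken by the earliest
#' starting month (January first). BIO8/BIO9 are the mean temperature of
#' the wettest/driest quarter (by precipitation sum), BIO10/BIO11 of the
#' warmest/coldest quarter (by temperature), BIO16/BIO17 the precipitation
#' of the wettest/driest quarter, BIO18/BIO19 of the warmest/coldest.
#' Cells with BIO7 = 0 get nodata BIO3, with a warning.
#'
#' @param normals A [climate_normals()].
#' @return A [bioclim_stack()].
#' @export
compute_bioclim <- function(normals) {
  spec <- normals$spec
  as_mat <- function(grids)
    do.call(cbind, lapply(grids, function(g) as.vector(g$values)))
  Tn <- as_mat(normals$tmin); Tx <- as_mat(normals$tmax)
  P  <- as_mat(normals$prec)
  ok <- rowSums(is.na(Tn)) == 0 & rowSums(is.na(Tx)) == 0 &
    rowSums(is.na(P)) == 0
  Tm <- (Tx + Tn) / 2

  n_cell <- nrow(Tn)
  b <- matrix(NA_real_, n_cell, 19)
  i <- which(ok)
  Tn <- Tn[i, , drop = FALSE]; Tx <- Tx[i, , drop = FALSE]
  Tm <- Tm[i, , drop = FALSE]; P <- P[i, , drop = FALSE]

  row_sd <- function(M) {
    mu <- rowMeans(M)
    sqrt(rowSums((M - mu)^2) / (ncol(M) - 1))
  }
  b[i, 1]  <- rowMeans(Tm)
  b[i, 2]  <- rowMeans(Tx - Tn)
  b[i, 4]  <- 100 * row_sd(Tm)
  b[i, 5]  <- apply(Tx, 1, max)
  b[i, 6]  <- apply(Tn, 1, min)
  b[i, 7]  <- b[i, 5] - b[i, 6]
  bio3 <- 100 * b[i, 2] / b[i, 7]
  flat <- b[i, 7] == 0
  if (any(flat)) {
    warning("compute_bioclim: BIO7 = 0 at ", sum(flat),
            " cell(s); BIO3 set to nodata there")
    bio3[flat] <- NA_real_
  }
  b[i, 3]  <- bio3
  b[i, 12] <- rowSums(P)
  b[i, 13] <- apply(P, 1, max)
  b[i, 14] <- apply(P, 1, min)
  b[i, 15] <- 100 * row_sd(P) / (1 + rowMeans(P))

  Q <- quarter_matrix()
  qP <- P %*% Q            # quarter precipitation sums
  qT <- (Tm %*% Q) / 3     # quarter mean temperatures
  pick <- function(M, q) M[cbind(seq_len(nrow(M)), q)]
  wetq  <- max.col(qP,  ties.method = "first")
  dryq  <- max.col(-qP, ties.method = "first")
  warmq <- max.col(qT,  ties.method = "first")
  coldq <- max.col(-qT, ties.method = "first")
  b[i, 8]  <- pick(qT, wetq)
  b[i, 9]  <- pick(qT, dryq)
  b[i, 10] <- pick(qT, warmq)
  b[i, 11] <- pick(qT, coldq)
  b[i, 16] <- pick(qP, wetq)
  b[i, 17] <- pick(qP, dryq)
  b[i, 18] <- pick(qP, warmq)
  b[i, 19] <- pick(qP, coldq)

  bio <- lapply(1:19, function(k)
    raster_grid(matrix(b[, k], spec$n_rows, spec$n_cols), spec))
  bioclim_stack(bio, normals$window)
}

#' Prune correlated bioclim predictors
#'
#' Computes pairwise Pearson correlations over the jointly valid cells and
#' retains a maximal set of mutually weakly correlated variables by a
#' greedy scan in priority order: a variable is retained iff its |r|
#' against every already-retained variable is at most `threshold`; a
#' dropped variable records the retained partner it correlates with most
#' strongly. Zero-variance layers are excluded with a warning.
#'
#' The default priority (BIO6, BIO12, BIO2, BIO5, BIO15, BIO18, then the
#' remaining indices in ascending order) encodes the coastal-ecology
#' preference for minimum temperature of the coldest month and annual
#' precipitation as the anchor predictors of mangrove and salt-marsh range
#' limits.
#'
#' @param stack A [bioclim_stack()].
#' @param threshold Maximum absolute Pearson correlation allowed between
#'   retained variables (default 0.7).
#' @param priority Integer vector of BIO indices in scan order.
#' @return An object of class `predictor_set`: `retained` (BIO indices)
#'   and `dropped` (data frame `dropped`, `kept`, `r`).
#' @export
correlation_prune <- function(stack, threshold = 0.7,
                              priority = c(6, 12, 2, 5, 15, 18)) {
  priority <- c(priority, setdiff(1:19, priority))
  M <- do.call(cbind, lapply(stack$bio, function(g) as.vector(g$values)))
  ok <- rowSums(is.na(M)) == 0
  if (sum(ok) < 2)
    stop("correlation_prune: fewer than 2 jointly valid cells")
  M <- M[ok, , drop = FALSE]
  sds <- apply(M, 2, stats::sd)
  degenerate <- which(sds == 0)
  if (length(degenerate))
    warning("correlation_prune: zero-variance layer(s) excluded: ",
            paste0("BIO", degenerate, collapse = ", "))
  R <- suppressWarnings(stats::cor(M))
  retained <- integer(0)
  dropped <- data.frame(dropped = integer(0), kept = integer(0),
                        r = numeric(0))
  for (v in priority) {
    if (v %in% degenerate) next
    r_v <- abs(R[v, retained])
    if (length(retained) && any(r_v > threshold)) {
      j <- retained[which.max(r_v)]
      dropped <- rbind(dropped,
                       data.frame(dropped = v, kept = j, r = R[v, j]))
    } else {
      retained <- c(retained, v)
    }
  }
  structure(list(retained = sort(retained), dropped = dropped,
                 threshold = threshold),
            class = "predictor_set")
}

#' @export
print.predictor_set <- function(x, ...) {
  cat("predictor_set: retained",
      paste0("BIO", x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped))
    cat(sprintf("  dropped %d variable(s) at |r| > %g\n",
                nrow(x$dropped), x$threshold))
  invisible(x)
}

#' Subset a bioclim stack to selected variables
#'
#' @param stack A [bioclim_stack()].
#' @param vars Integer BIO indices to keep.
#' @return A named list of [raster_grid()]s (`bio<k>`), the environmental
#'   layer set used for modeling.
#' @export
select_predictors <- function(stack, vars) {
  out <- stack$bio[paste0("bio", vars)]
  attr(out, "window") <- stack$window
  out
}
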