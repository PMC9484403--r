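#' Synthetic climate scenario
#'
#' Describes a desk-scale synthetic analogue of a monthly gridded climate
#' archive: a latitudinal temperature gradient, a sinusoidal seasonal
#' cycle, a longitudinal (coast-to-inland) precipitation gradient with its
#' own seasonality,
#' white observation noise, and named multi-year periods carrying additive
#' temperature/precipitation offsets (used to emulate cold/wet versus
#' warm/dry dominance oscillations in the past and warming in the future).
#'
#' The default geometry (60 x 80 cells of 1 degree, lon -112..-32, lat
#' -30..30) spans tropical to subtropical latitudes of a synthetic
#' coastline at a size where every full-pipeline experiment runs in
#' seconds.
#'
#' @param grid A [grid_spec()].
#' @param periods Named list; each element a list with `years = c(start,
#'   end)` and optional `temp` (deg C) and `prec` (mm/month) offsets.
#' @param base_temp Annual-mean temperature at the equator (deg C).
#' @param lapse Cooling per degree of absolute latitude (deg C / degree).
#' @param amplitude Seasonal temperature half-amplitude (deg C).
#' @param peak_month Month of the seasonal temperature peak.
#' @param diurnal_range tmax - tmin (deg C), constant.
#' @param prec_base Monthly precipitation at the equator (mm).
#' @param prec_gradient Drying per degree of longitude east of the west
#'   (coastal) edge (mm/degree). Running the moisture gradient along
#'   longitude keeps it orthogonal to the latitudinal temperature
#'   gradient, so the cold-limited and moisture-limited suitability
#'   drivers are statistically separable across the landscape.
#' @param prec_amplitude Seasonal precipitation half-amplitude (mm).
#' @param temp_noise_sd,prec_noise_sd White-noise standard deviations.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `climate_scenario`.
#' @export
climate_scenario <- function(grid = grid_spec(-112, -30, -32, 30, 1),
                             periods = list(
                               present = list(years = c(2013, 2018)),
                               saltmarsh_dom = list(years = c(1984, 1989),
                                                    temp = -2.5, prec = 50),
                               mangrove_dom = list(years = c(2001, 2006),
                                                   temp = 0.5, prec = -40)),
                             base_temp = 27, lapse = 0.45, amplitude = 6,
                             peak_month = 7, diurnal_range = 8,
                             prec_base = 180, prec_gradient = 1.5,
                             prec_amplitude = 60,
                             temp_noise_sd = 0.3, prec_noise_sd = 8,
                             seed = 1) {
  structure(list(grid = grid, periods = periods, base_temp = base_temp,
                 lapse = lapse, amplitude = amplitude,
                 peak_month = peak_month, diurnal_range = diurnal_range,
                 prec_base = prec_base, prec_gradient = prec_gradient,
                 prec_amplitude = prec_amplitude,
                 temp_noise_sd = temp_noise_sd,
                 prec_noise_sd = prec_noise_sd, seed = seed),
            class = "climate_scenario")
}

#' Generate the per-year monthly climate series of a scenario
#'
#' For each year of each period and each month, cell temperature is
#' `base - lapse * |lat| + amplitude * cos(2 pi (month - peak)/12) +
#' period offset + noise`; tmin/tmax are tmean -/+ half the diurnal
#' range. Precipitation is `prec_base - prec_gradient * (lon - west) +
#' prec_amplitude * cos(...) + period offset + noise`, floored at 0.
#'
#' @param scenario A [climate_scenario()].
#' @return Named list (one element per year, names = years), each with
#'   `tmin`, `tmax`, `prec` lists of 12 [raster_grid()]s — the input
#'   format of [window_average()].
#' @export
generate_climate <- function(scenario) {
  s <- scenario; g <- s$grid
  lat <- matrix(rep(cell_lats(g), g$n_cols), g$n_rows, g$n_cols)
  lon_east <- matrix(rep(cell_lons(g) - g$west, each = g$n_rows),
                     g$n_rows, g$n_cols)
  years <- unlist(lapply(s$periods, function(p) seq(p$years[1], p$years[2])))
  offset_of <- function(year) {
    for (p in s$periods)
      if (year >= p$years[1] && year <= p$years[2])
        return(c(temp = if (is.null(p$temp)) 0 else p$temp,
                 prec = if (is.null(p$prec)) 0 else p$prec))
    c(temp = 0, prec = 0)
  }
  with_seed(s$seed, {
    out <- list()
    for (y in sort(unique(years))) {
      off <- offset_of(y)
      tmin <- tmax <- prec <- vector("list", 12)
      for (m in 1:12) {
        seas <- cos(2 * pi * (m - s$peak_month) / 12)
        tmean <- s$base_temp - s$lapse * abs(lat) + s$amplitude * seas +
          off["temp"] +
          matrix(stats::rnorm(length(lat), sd = s$temp_noise_sd),
                 nrow(lat), ncol(lat))
        p <- s$prec_base - s$prec_gradient * lon_east +
          s$prec_amplitude * seas + off["prec"] +
          matrix(stats::rnorm(length(lat), sd = s$prec_noise_sd),
                 nrow(lat), ncol(lat))
        tmin[[m]] <- raster_grid(tmean - s$diurnal_range / 2, g)
        tmax[[m]] <- raster_grid(tmean + s$diurnal_range / 2, g)
        prec[[m]] <- raster_grid(pmax(p, 0), g)
      }
      out[[as.character(y)]] <- list(tmin = tmin, tmax = tmax, prec = prec)
    }
    out
  })
}

#' Generate a synthetic elevation surface
#'
#' A low-lying coastal band along the western edge of the grid (elevations
#' uniform in 0..9 m) rising steeply inland (well above the 10 m cutoff),
#' so the downstream elevation mask keeps exactly the coastal band. The
#' band width can be given directly in cells or via the fraction of cells
#' the mask should remove.
#'
#' @param grid A [grid_spec()].
#' @param coastal_band_cells Width of the low-elevation band in columns
#'   from the west edge; `grid$n_cols` keeps every cell, 0 masks all.
#' @param maskable_fraction Alternative to `coastal_band_cells`: the
#'   fraction of cells that should exceed the 10 m cutoff.
#' @param seed Integer seed.
#' @return A [raster_grid()] of elevations in meters.
#' @export
generate_elevation <- function(grid, coastal_band_cells = NULL,
                               maskable_fraction = NULL, seed = 1) {
  if (is.null(coastal_band_cells)) {
    if (is.null(maskable_fraction))
      stop("generate_elevation: give coastal_band_cells or maskable_fraction")
    coastal_band_cells <- round((1 - maskable_fraction) * grid$n_cols)
  }
  with_seed(seed, {
    elev <- matrix(NA_real_, grid$n_rows, grid$n_cols)
    for (j in seq_len(grid$n_cols)) {
      elev[, j] <- if (j <= coastal_band_cells)
        stats::runif(grid$n_rows, 0, 9)
      else
        15 + 5 * (j - coastal_band_cells) +
          stats::runif(grid$n_rows, 0, 4)
    }
    raster_grid(elev, grid)
  })
}

#' Ground-truth suitability model for occurrence sampling
#'
#' An exponential (log-linear) sampling density over the landscape:
#' `P(cell) proportional to exp(intercept + sum coef_v * env_v)`.
#'
#' @param coefficients Named numeric vector; names are layer names (e.g.
#'   `bio6`).
#' @param intercept Intercept of the linear predictor.
#' @return An object of class `truth_model`.
#' @export
truth_model <- function(coefficients, intercept = 0) {
  stopifnot(!is.null(names(coefficients)), all(is.finite(coefficients)))
  structure(list(coefficients = coefficients, intercept = intercept),
            class = "truth_model")
}

truth_eta <- function(truth, env) {
  missing <- setdiff(names(truth$coefficients), colnames(env))
  if (length(missing))
    stop("truth_model: environment missing variable(s): ",
         paste(missing, collapse = ", "))
  truth$intercept +
    as.vector(env[, names(truth$coefficients), drop = FALSE] %*%
                truth$coefficients)
}

#' Sample occurrences from a truth model
#'
#' Samples `m` cells (with replacement) with probability proportional to
#' `exp(eta_truth)` over the jointly valid cells of the layers, then
#' jitters each point uniformly within its cell. Optional contamination
#' injects exact duplicates and (0, 0) records to exercise the cleaning
#' rules.
#'
#' @param truth A [truth_model()].
#' @param layers Named list of [raster_grid()]s containing the truth
#'   variables.
#' @param m Number of occurrence records.
#' @param seed Integer seed.
#' @param species Species name attached to the records.
#' @param jitter Jitter points uniformly within their cells (default TRUE).
#' @param contaminate Optional list with counts `duplicates` and
#'   `zero_zero` of bad records to append.
#' @return Data frame `species`, `longitude`, `latitude` (raw records, to
#'   be passed through [clean_occurrences()]).
#' @export
generate_occurrences <- function(truth, layers, m, seed = 1,
                                 species = "synthetic_species",
                                 jitter = TRUE, contaminate = NULL) {
  env <- env_at(layers)
  cells <- attr(env, "cell")
  eta <- truth_eta(truth, env)
  pr <- exp(eta - max(eta))
  pr <- pr / sum(pr)
  if (max(pr) > 0.999)
    stop("generate_occurrences: degenerate truth (all mass on one cell)")
  spec <- layers[[1]]$spec
  with_seed(seed, {
    idx <- sample(seq_along(cells), m, replace = TRUE, prob = pr)
    cell <- cells[idx]
    row <- (cell - 1) %% spec$n_rows + 1
    col <- (cell - 1) %/% spec$n_rows + 1
    lon <- cell_lons(spec)[col]
    lat <- cell_lats(spec)[row]
    if (jitter) {
      lon <- lon + stats::runif(m, -0.5, 0.5) * spec$cell_size
      lat <- lat + stats::runif(m, -0.5, 0.5) * spec$cell_size
    }
    df <- data.frame(species = species, longitude = lon, latitude = lat)
    if (!is.null(contaminate)) {
      nd <- contaminate$duplicates %||% 0
      nz <- contaminate$zero_zero %||% 0
      if (nd > 0) df <- rbind(df, df[rep(seq_len(min(nd, m)),
                                         length.out = nd), ])
      if (nz > 0) df <- rbind(df, data.frame(species = species,
                                             longitude = rep(0, nz),
                                             latitude = rep(0, nz)))
    }
    rownames(df) <- NULL
    df
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-group dominance scenario and end-to-end hindcast experiment
#'
#' Builds the discriminative synthetic experiment: two "mangrove-like"
#' species whose truth favors high minimum temperature of the coldest
#' month (bio6) and two "saltmarsh-like" species favoring high annual
#' precipitation (bio12), on a climate whose past periods carry a
#' cold/wet (salt-marsh dominance) and a warm/dry (mangrove dominance)
#' offset. Models are fitted on the present window from sampled
#' occurrences, hindcast onto the past windows, and the group-level
#' validation rule is applied. With `inverted = TRUE` the two past
#' offsets are swapped, which must break the validation.
#'
#' @param seed Integer seed for climate, sampling and fitting.
#' @param inverted Swap the past-period climate offsets.
#' @param m Occurrences per species.
#' @param n_background Background points.
#' @param classes,multiplier Model configuration for the fits.
#' @param region Validation [region_box()]; default is a band in the
#'   subtropical north of the synthetic grid where the two gradients
#'   trade off.
#' @return List with the `validation_report`, the `group_trajectory`,
#'   the fitted models and the per-window layer stacks.
#' @export
run_dominance_experiment <- function(seed = 1, inverted = FALSE, m = 400,
                                     n_background = 2000,
                                     classes = "LQ", multiplier = 1,
                                     region = region_box("north_band",
                                                         -112, -32, 10, 30)) {
  periods <- list(
    present = list(years = c(2013, 2018)),
    saltmarsh_dom = list(years = c(1984, 1989), temp = -2.5, prec = 50),
    mangrove_dom = list(years = c(2001, 2006), temp = 0.5, prec = -40))
  if (inverted) {
    tmp <- periods$saltmarsh_dom[c("temp", "prec")]
    periods$saltmarsh_dom[c("temp", "prec")] <-
      periods$mangrove_dom[c("temp", "prec")]
    periods$mangrove_dom[c("temp", "prec")] <- tmp
  }
  scen <- climate_scenario(periods = periods, seed = seed)
  series <- generate_climate(scen)
  full_stacks <- lapply(periods, function(p)
    compute_bioclim(window_average(series, p$years)))
  # prune on the training (present) window, as the pipeline does; the
  # synthetic temperature variables are strongly collinear by construction
  pruned <- suppressWarnings(correlation_prune(full_stacks$present))
  stacks <- lapply(full_stacks, select_predictors, vars = pruned$retained)
  truths <- list(
    mangrove_a = truth_model(c(bio6 = 0.55)),
    mangrove_b = truth_model(c(bio6 = 0.45, bio12 = 0.0005)),
    saltmarsh_a = truth_model(c(bio12 = 0.008)),
    saltmarsh_b = truth_model(c(bio12 = 0.0065, bio6 = 0.05)))
  groups <- c(mangrove_a = "mangrove", mangrove_b = "mangrove",
              saltmarsh_a = "saltmarsh", saltmarsh_b = "saltmarsh")
  bg <- sample_background(stacks$present, n = n_background, seed = seed)
  bg_env <- env_at(stacks$present, bg$longitude, bg$latitude)
  models <- lapply(names(truths), function(sp) {
    occ_raw <- generate_occurrences(truths[[sp]], stacks$present, m,
                                    seed = seed + match(sp, names(truths)),
                                    species = sp)
    occ <- clean_occurrences(occ_raw, extent = scen$grid)
    p_env <- env_at(stacks$present, occ$records$longitude,
                    occ$records$latitude)
    keep <- rowSums(is.na(p_env)) == 0
    suppressWarnings(maxent_fit(p_env[keep, , drop = FALSE], bg_env,
                                classes = classes,
                                multiplier = multiplier))
  })
  names(models) <- names(truths)
  maps <- lapply(stacks, function(st)
    lapply(models, function(mod) predict(mod, st)))
  traj <- project_timeline(maps, list(region), groups)
  gm <- traj$group_means
  get_means <- function(grp) {
    v <- gm$S_mean[gm$group == grp]
    names(v) <- gm$window[gm$group == grp]
    v[c("saltmarsh_dom", "mangrove_dom", "present")]
  }
  report <- hindcast_validate(get_means("mangrove"), get_means("saltmarsh"),
                              region = region$name)
  list(report = report, trajectory = traj, models = models,
       stacks = stacks, groups = groups)
}
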