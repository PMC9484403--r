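#' Default pipeline configuration
#'
#' Returns the full run configuration with every analysis default
#' pre-filled: the 2.5-arc-minute-era study extent (-120..-32 lon,
#' -36..36 lat), the six named time windows (present 2013-2018, past
#' dominance periods 1984-1989 and 2001-2006, futures 2021-2040,
#' 2041-2060, 2061-2080), the NE Florida and Florida validation regions,
#' the correlation threshold (0.7), elevation cutoff (10 m), minimum
#' occurrence count (50), background size (10,000) and the tuning grid
#' (six feature-class combinations x multipliers 0.5..4). The `scenario`
#' section configures the synthetic generator used by the `simulate`
#' stage; synthetic runs override extent and window years from it.
#'
#' @return Nested list; serialize with [yaml::write_yaml()] to obtain a
#'   config file.
#' @export
default_config <- function() {
  list(
    paths = list(output = "pipeline_out"),
    extent = list(west = -120, east = -32, south = -36, north = 36),
    windows = list(
      present = c(2013, 2018),
      saltmarsh_dom = c(1984, 1989),
      mangrove_dom = c(2001, 2006),
      future_2021_2040 = c(2021, 2040),
      future_2041_2060 = c(2041, 2060),
      future_2061_2080 = c(2061, 2080)),
    regions = list(
      ne_florida = list(west = -82, east = -80, south = 28, north = 31),
      florida = list(west = -87, east = -79, south = 24, north = 31),
      # subtropical band of the synthetic landscape where the thermal and
      # moisture gradients trade off; the hindcast verdict region for
      # synthetic runs (the real validation boxes cover too few cells of
      # the coarse synthetic grid to average over)
      synthetic_ecotone = list(west = -112, east = -32, south = 10,
                               north = 30)),
    thresholds = list(correlation = 0.7, elevation_m = 10,
                      n_min = 50, n_background = 10000),
    model = list(classes = "LQ", multiplier = 1, tune = FALSE,
                 classes_grid = c("L", "LQ", "LQH", "LQHP", "LQPT",
                                  "LQHPT"),
                 multipliers = seq(0.5, 4, by = 0.5)),
    groups = list(mangrove = c("mangrove_a", "mangrove_b"),
                  saltmarsh = c("saltmarsh_a", "saltmarsh_b")),
    scenario = list(synthetic = TRUE, m = 400, n_background = 2000,
                    inverted = FALSE,
                    validation_region = "synthetic_ecotone"),
    seed = 1)
}

#' Read and validate a pipeline config file
#'
#' @param path YAML file path.
#' @return Validated config list (defaults filled for absent fields).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(utils::modifyList(default_config(), cfg))
}

validate_config <- function(cfg) {
  for (f in c("paths", "extent", "windows", "regions", "thresholds",
              "groups", "seed"))
    if (is.null(cfg[[f]]))
      stop("config: missing required field '", f, "'")
  for (f in c("west", "east", "south", "north"))
    if (is.null(cfg$extent[[f]]))
      stop("config: missing required field 'extent.", f, "'")
  for (w in names(cfg$windows)) {
    y <- cfg$windows[[w]]
    if (length(y) != 2 || y[2] < y[1])
      stop("config: invalid field 'windows.", w, "'")
  }
  sp <- unlist(cfg$groups, use.names = FALSE)
  if (anyDuplicated(sp))
    stop("config: species assigned to more than one group: ",
         paste(sp[duplicated(sp)], collapse = ", "))
  cfg
}

pipeline_stages <- c("simulate", "bioclim", "prune", "fit", "evaluate",
                     "project", "aggregate", "validate", "report")

#' Run the modeling pipeline
#'
#' Executes the pipeline stages in order up to `stage`, writing versioned
#' artifacts (ASCII grids, CSV tables, JSON model files) under the
#' config's output directory together with a machine-readable run
#' manifest (inputs, seed, package version, stage timings, artifact
#' checksums). Stages: `simulate` (synthetic climate, elevation and
#' occurrences), `bioclim` (window averages and the 19 variables per
#' window), `prune` (correlation pruning on the present window), `fit`
#' (background sampling and per-species model fits, with optional AICc
#' tuning), `evaluate` (cross-validation, partial ROC, jackknife,
#' contributions), `project` (suitability maps per species x window),
#' `aggregate` (region sums, group means, ratios, percent changes),
#' `validate` (hindcast decision rule), `report` (everything).
#' Re-running with the same config and seed reproduces identical outputs.
#'
#' @param config Config list (see [default_config()]) or path to a YAML
#'   file.
#' @param stage Last stage to run (default `"report"`).
#' @param seed Overrides the config seed when given.
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, a list with the stage outputs (`stacks`, `models`,
#'   `trajectory`, `validation`, `manifest`).
#' @export
run_pipeline <- function(config = default_config(), stage = "report",
                         seed = NULL, verbose = FALSE) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  if (!is.null(seed)) config$seed <- seed
  stage <- match.arg(stage, pipeline_stages)
  n_stage <- match(stage, pipeline_stages)
  out_dir <- config$paths$output
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- function(...) if (verbose) message("[pipeline] ", ...)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(name) {
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    t0 <<- proc.time()[["elapsed"]]
  }
  state <- list(config = config)

  if (!isTRUE(config$scenario$synthetic))
    stop("run_pipeline: only synthetic scenarios are supported in this ",
         "build; supply externally computed grids via the module ",
         "functions directly")

  # -- simulate ------------------------------------------------------------
  log("simulate")
  periods <- list(
    present = list(years = unlist(config$windows$present)),
    saltmarsh_dom = list(years = unlist(config$windows$saltmarsh_dom),
                         temp = -2.5, prec = 50),
    mangrove_dom = list(years = unlist(config$windows$mangrove_dom),
                        temp = 0.5, prec = -40))
  fut <- grep("^future", names(config$windows), value = TRUE)
  for (i in seq_along(fut))
    periods[[fut[i]]] <- list(years = unlist(config$windows[[fut[i]]]),
                              temp = 0.8 * i, prec = -12 * i)
  if (isTRUE(config$scenario$inverted)) {
    tmp <- periods$saltmarsh_dom[c("temp", "prec")]
    periods$saltmarsh_dom[c("temp", "prec")] <-
      periods$mangrove_dom[c("temp", "prec")]
    periods$mangrove_dom[c("temp", "prec")] <- tmp
  }
  scen <- climate_scenario(periods = periods, seed = config$seed)
  series <- generate_climate(scen)
  elev <- generate_elevation(scen$grid, coastal_band_cells = scen$grid$n_cols,
                             seed = config$seed)
  state$series <- series
  tick("simulate")
  if (n_stage < match("bioclim", pipeline_stages))
    return(invisible(finish_pipeline(state, out_dir, timings, log)))

  # -- bioclim -------------------------------------------------------------
  log("bioclim")
  full_stacks <- lapply(periods, function(p)
    compute_bioclim(window_average(series, p$years)))
  cutoff <- config$thresholds$elevation_m
  masked <- lapply(full_stacks, function(st) {
    st$bio <- lapply(st$bio, elevation_mask, elevation = elev,
                     cutoff_m = cutoff)
    st
  })
  state$stacks_full <- masked
  tick("bioclim")
  if (n_stage < match("prune", pipeline_stages))
    return(invisible(finish_pipeline(state, out_dir, timings, log)))

  # -- prune ---------------------------------------------------------------
  log("prune")
  pruned <- suppressWarnings(
    correlation_prune(masked$present,
                      threshold = config$thresholds$correlation))
  state$predictors <- pruned
  stacks <- lapply(masked, select_predictors, vars = pruned$retained)
  state$stacks <- stacks
  prune_df <- data.frame(
    variable = paste0("BIO", 1:19),
    status = ifelse(1:19 %in% pruned$retained, "retained",
                    ifelse(1:19 %in% pruned$dropped$dropped, "dropped",
                           "excluded")),
    partner = NA_character_, r = NA_real_)
  if (nrow(pruned$dropped)) {
    i <- match(pruned$dropped$dropped, 1:19)
    prune_df$partner[i] <- paste0("BIO", pruned$dropped$kept)
    prune_df$r[i] <- pruned$dropped$r
  }
  utils::write.csv(prune_df, file.path(out_dir, "predictors.csv"),
                   row.names = FALSE)
  tick("prune")
  if (n_stage < match("fit", pipeline_stages))
    return(invisible(finish_pipeline(state, out_dir, timings, log)))

  # -- fit -----------------------------------------------------------------
  log("fit")
  truths <- list(
    mangrove_a = truth_model(c(bio6 = 0.55)),
    mangrove_b = truth_model(c(bio6 = 0.45, bio12 = 0.0005)),
    saltmarsh_a = truth_model(c(bio12 = 0.008)),
    saltmarsh_b = truth_model(c(bio12 = 0.0065, bio6 = 0.05)))
  groups <- stats::setNames(
    rep(names(config$groups), lengths(config$groups)),
    unlist(config$groups, use.names = FALSE))
  species <- names(groups)
  if (length(species) != 4)
    truths <- truths[seq_along(species)]
  names(truths) <- species
  bg <- sample_background(stacks$present,
                          n = config$scenario$n_background,
                          seed = config$seed)
  bg_env <- env_at(stacks$present, bg$longitude, bg$latitude)
  occs <- list(); models <- list()
  for (sp in species) {
    raw <- generate_occurrences(truths[[sp]], stacks$present,
                                m = config$scenario$m,
                                seed = config$seed + match(sp, species),
                                species = sp)
    write_occurrences(raw, file.path(out_dir, paste0("occ_raw_", sp, ".csv")))
    occ <- clean_occurrences(raw, extent = config$extent)
    if (!min_occurrence_filter(occ, config$thresholds$n_min))
      stop("run_pipeline: species ", sp, " fails the minimum occurrence ",
           "gate (", nrow(occ$records), " < ", config$thresholds$n_min, ")")
    occs[[sp]] <- occ
    p_env <- env_at(stacks$present, occ$records$longitude,
                    occ$records$latitude)
    p_env <- p_env[rowSums(is.na(p_env)) == 0, , drop = FALSE]
    if (isTRUE(config$model$tune)) {
      bins <- checkerboard2_partition(occ$records$longitude,
                                      occ$records$latitude,
                                      stacks$present[[1]]$spec)
      tuned <- tune_sdm(p_env, bg_env,
                        classes_grid = config$model$classes_grid,
                        multipliers = config$model$multipliers,
                        partition_bins = bins)
      models[[sp]] <- tuned$best
      utils::write.csv(tuned$grid,
                       file.path(out_dir, paste0("tuning_", sp, ".csv")),
                       row.names = FALSE)
    } else {
      models[[sp]] <- suppressWarnings(
        maxent_fit(p_env, bg_env, classes = config$model$classes,
                   multiplier = config$model$multiplier))
    }
    write_maxent_model(models[[sp]],
                       file.path(out_dir, paste0("model_", sp, ".json")))
  }
  state$models <- models; state$occurrences <- occs; state$bg_env <- bg_env
  tick("fit")
  if (n_stage >= match("evaluate", pipeline_stages)) {
    log("evaluate")
    eval_rows <- lapply(species, function(sp) {
      mod <- models[[sp]]
      occ <- occs[[sp]]
      p_env <- mod$p_env
      cv <- kfold_cv(p_env, bg_env, classes = config$model$classes,
                     multiplier = config$model$multiplier, k = 5,
                     seed = config$seed, n_boot = 100)
      pr <- partial_roc(predict(mod, p_env), predict(mod, bg_env),
                        n_boot = 200, seed = config$seed)
      contrib <- percent_contribution(mod)
      data.frame(species = sp, mean_cv_omission = cv$mean_omission,
                 proc_ratio = pr$proc_ratio, proc_p = pr$proc_p,
                 t(contrib))
    })
    eval_df <- do.call(rbind, eval_rows)
    utils::write.csv(eval_df, file.path(out_dir, "evaluation.csv"),
                     row.names = FALSE)
    jk <- lapply(species, function(sp) {
      j <- jackknife_gain(models[[sp]]$p_env, bg_env,
                          classes = config$model$classes,
                          multiplier = config$model$multiplier)
      cbind(species = sp, j)
    })
    utils::write.csv(do.call(rbind, jk),
                     file.path(out_dir, "jackknife.csv"), row.names = FALSE)
    state$evaluation <- eval_df
    tick("evaluate")
  }
  if (n_stage < match("project", pipeline_stages))
    return(invisible(finish_pipeline(state, out_dir, timings, log)))

  # -- project -------------------------------------------------------------
  log("project")
  maps <- lapply(stacks, function(st)
    lapply(models, function(mod) predict(mod, st)))
  for (w in names(maps)) for (sp in names(maps[[w]]))
    write_raster(maps[[w]][[sp]],
                 file.path(out_dir, sprintf("suitability_%s_%s.asc", sp, w)))
  state$maps <- maps
  tick("project")
  if (n_stage < match("aggregate", pipeline_stages))
    return(invisible(finish_pipeline(state, out_dir, timings, log)))

  # -- aggregate -----------------------------------------------------------
  log("aggregate")
  regions <- c(lapply(names(config$regions), function(r)
    do.call(region_box, c(list(name = r), config$regions[[r]]))),
    list(NULL))
  traj <- project_timeline(maps, regions, groups)
  rep_tables <- trajectory_report(traj)
  utils::write.csv(rep_tables$sums, file.path(out_dir, "suitability_sums.csv"),
                   row.names = FALSE)
  utils::write.csv(rep_tables$ratios, file.path(out_dir, "ratios.csv"),
                   row.names = FALSE)
  utils::write.csv(rep_tables$group_change,
                   file.path(out_dir, "group_percent_change.csv"),
                   row.names = FALSE)
  utils::write.csv(rep_tables$species_change,
                   file.path(out_dir, "species_percent_change.csv"),
                   row.names = FALSE)
  state$trajectory <- traj
  tick("aggregate")
  if (n_stage < match("validate", pipeline_stages))
    return(invisible(finish_pipeline(state, out_dir, timings, log)))

  # -- validate ------------------------------------------------------------
  log("validate")
  gm <- traj$group_means
  first_region <- config$scenario$validation_region %||%
    if (length(names(config$regions))) names(config$regions)[1] else
      "full_extent"
  if (!first_region %in% gm$region)
    stop("run_pipeline: validation region '", first_region,
         "' is not among the aggregated regions")
  get_means <- function(grp) {
    sel <- gm$group == grp & gm$region == first_region
    v <- gm$S_mean[sel]; names(v) <- gm$window[sel]
    v[c("saltmarsh_dom", "mangrove_dom", "present")]
  }
  validation <- hindcast_validate(get_means("mangrove"),
                                  get_means("saltmarsh"),
                                  region = first_region)
  utils::write.csv(
    data.frame(region = first_region,
               criterion = c("A", "B", "C", "verdict"),
               value = c(validation$criteria, validation$verdict)),
    file.path(out_dir, "validation.csv"), row.names = FALSE)
  state$validation <- validation
  tick("validate")

  invisible(finish_pipeline(state, out_dir, timings, log))
}

finish_pipeline <- function(state, out_dir, timings, log) {
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  sums <- vapply(file.path(out_dir, files), function(f)
    unname(tools::md5sum(f)), character(1))
  manifest <- list(
    package_version = as.character(utils::packageVersion("hindcastSDM")),
    seed = state$config$seed,
    timings_s = timings,
    artifacts = stats::setNames(as.list(unname(sums)), files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  state$manifest <- manifest
  log("done")
  state
}
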