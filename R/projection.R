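#' Rectangular analysis region
#'
#' @param name Region name.
#' @param west,east,south,north Bounds in decimal degrees. The defaults of
#'   the pipeline config define the NE Florida ecotone validation box
#'   (-82..-80 lon, 28..31 lat) and the larger Florida box (-87..-79 lon,
#'   24..31 lat).
#' @return An object of class `region_box`.
#' @export
region_box <- function(name, west, east, south, north) {
  if (east <= west || north <= south)
    stop("region_box: need east > west and north > south")
  structure(list(name = name, west = west, east = east, south = south,
                 north = north), class = "region_box")
}

#' Total suitable habitat in a region
#'
#' The sum of cloglog suitability values over the valid cells whose
#' centers fall inside the region (inclusive bounds); nodata cells are
#' excluded. This suitability sum is the pipeline's measure of total
#' suitable habitat.
#'
#' @param map A `suitability_grid` (or any [raster_grid()]).
#' @param region A [region_box()]; omit to sum over the whole map.
#' @return The sum S (a single non-negative number for cloglog maps).
#' @export
total_suitability <- function(map, region = NULL) {
  v <- map$values
  if (!is.null(region)) {
    lons <- cell_lons(map$spec); lats <- cell_lats(map$spec)
    in_c <- lons >= region$west & lons <= region$east
    in_r <- lats >= region$south & lats <= region$north
    if (!any(in_c) || !any(in_r))
      stop("total_suitability: region does not overlap the map")
    v <- v[in_r, in_c, drop = FALSE]
  }
  sum(v, na.rm = TRUE)
}

#' Group average suitability
#'
#' Arithmetic mean of the member species' suitability sums.
#'
#' @param S Numeric vector of per-species suitability sums.
#' @return The group mean.
#' @export
group_average <- function(S) {
  if (!length(S)) stop("group_average: empty group")
  mean(S)
}

#' Percent change in suitability relative to the present
#'
#' @param S_t Suitability sum in the target period.
#' @param S_present Suitability sum in the present (must be positive).
#' @return `100 * (S_t - S_present) / S_present`.
#' @export
percent_change <- function(S_t, S_present) {
  if (any(S_present <= 0)) stop("percent_change: S_present must be positive")
  100 * (S_t - S_present) / S_present
}

#' Mangrove:salt-marsh suitability ratio
#'
#' @param S_mangrove,S_saltmarsh Group-average suitability sums.
#' @return `S_mangrove / S_saltmarsh`.
#' @export
suitability_ratio <- function(S_mangrove, S_saltmarsh) {
  if (any(S_saltmarsh <= 0))
    stop("suitability_ratio: salt-marsh group average must be positive")
  S_mangrove / S_saltmarsh
}

#' Hindcast validation decision rule
#'
#' Formalizes the ordinal expectation that in a past period dominated by
#' one group, the model should show that group relatively favored. Given
#' group-average suitability sums for the salt-marsh dominance period, the
#' mangrove dominance period and the present, the criteria are:
#' \describe{
#'   \item{A}{mangrove average is lower in the salt-marsh dominance period
#'     than in the mangrove dominance period}
#'   \item{B}{salt-marsh average is lower in the mangrove dominance period
#'     than in the salt-marsh dominance period}
#'   \item{C}{the mangrove:salt-marsh ratio is higher in the mangrove
#'     dominance period than in the salt-marsh dominance period}
#' }
#' The verdict is the conjunction of the three, computed on unrounded
#' values. Species-level orderings, when per-species sums are supplied,
#' are reported for information only and do not affect the verdict:
#' individual species may deviate from the group trend without failing
#' the validation.
#'
#' @param mangrove,saltmarsh Named numeric vectors of group-average sums
#'   with elements `saltmarsh_dom`, `mangrove_dom`, `present`.
#' @param species_S Optional matrix of per-species sums (rows named as the
#'   periods above, columns = species).
#' @param region Optional region name carried into the report.
#' @return An object of class `validation_report`: the three criteria,
#'   the verdict, the period ratios and any per-species orderings.
#' @export
hindcast_validate <- function(mangrove, saltmarsh, species_S = NULL,
                              region = NULL) {
  need <- c("saltmarsh_dom", "mangrove_dom", "present")
  if (!all(need %in% names(mangrove)) || !all(need %in% names(saltmarsh)))
    stop("hindcast_validate: missing period(s); need ",
         paste(need, collapse = ", "))
  ratio <- c(saltmarsh_dom = suitability_ratio(mangrove[["saltmarsh_dom"]],
                                               saltmarsh[["saltmarsh_dom"]]),
             mangrove_dom = suitability_ratio(mangrove[["mangrove_dom"]],
                                              saltmarsh[["mangrove_dom"]]))
  criteria <- c(
    A = unname(mangrove[["saltmarsh_dom"]] < mangrove[["mangrove_dom"]]),
    B = unname(saltmarsh[["mangrove_dom"]] < saltmarsh[["saltmarsh_dom"]]),
    C = unname(ratio[["mangrove_dom"]] > ratio[["saltmarsh_dom"]]))
  species_ordering <- NULL
  if (!is.null(species_S)) {
    species_ordering <- apply(species_S, 2, function(s)
      s["saltmarsh_dom"] < s["mangrove_dom"])
  }
  structure(list(region = region, criteria = criteria,
                 verdict = all(criteria), ratios = ratio,
                 mangrove = mangrove, saltmarsh = saltmarsh,
                 species_ordering = species_ordering),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("hindcast validation",
      if (!is.null(x$region)) paste0("(", x$region, ")"), "\n")
  cat(sprintf("  A (mangrove lower in salt-marsh period): %s\n", x$criteria["A"]))
  cat(sprintf("  B (salt marsh lower in mangrove period): %s\n", x$criteria["B"]))
  cat(sprintf("  C (ratio higher in mangrove period):     %s\n", x$criteria["C"]))
  cat(sprintf("  verdict: %s\n", if (x$verdict) "VALIDATED" else "NOT validated"))
  invisible(x)
}

#' Project suitability across time windows and aggregate by region/group
#'
#' Builds the full trajectory report: per-region and per-window species
#' suitability sums, group averages, mangrove:salt-marsh ratios, and
#' percent changes relative to the present window. Group percent change
#' is computed from the group-average sums (not as the mean of
#' species-level percent changes). Reported tables round sums to 1
#' decimal, ratios to 3 decimals and percent changes to 1 decimal; the
#' underlying comparisons elsewhere use unrounded values.
#'
#' @param maps Nested list: `maps[[window]][[species]]`, each a
#'   `suitability_grid`.
#' @param regions List of [region_box()]es (or `NULL` entries for the full
#'   map extent).
#' @param groups Named character vector mapping species to `"mangrove"` or
#'   `"saltmarsh"`.
#' @param present Name of the present window (default `"present"`).
#' @return An object of class `group_trajectory` with data frames `sums`
#'   (region, window, species, S, group), `group_means`, `ratios`,
#'   `group_change`, `species_change`.
#' @export
project_timeline <- function(maps, regions, groups, present = "present") {
  windows <- names(maps)
  if (!(present %in% windows))
    stop("project_timeline: present window '", present, "' missing")
  region_names <- vapply(regions, function(r)
    if (is.null(r)) "full_extent" else r$name, character(1))
  rows <- list()
  for (ri in seq_along(regions)) {
    for (w in windows) {
      for (sp in names(maps[[w]])) {
        rows[[length(rows) + 1L]] <- data.frame(
          region = region_names[ri], window = w, species = sp,
          S = total_suitability(maps[[w]][[sp]], regions[[ri]]),
          group = unname(groups[sp]))
      }
    }
  }
  sums <- do.call(rbind, rows)

  agg <- function(df) {
    means <- stats::aggregate(S ~ region + window + group, df, group_average)
    names(means)[names(means) == "S"] <- "S_mean"
    means
  }
  group_means <- agg(sums)

  wide <- stats::reshape(group_means, idvar = c("region", "window"),
                         timevar = "group", direction = "wide")
  ratios <- if (all(c("S_mean.mangrove", "S_mean.saltmarsh") %in%
                    names(wide))) {
    data.frame(region = wide$region, window = wide$window,
               ratio = suitability_ratio(wide$S_mean.mangrove,
                                         wide$S_mean.saltmarsh))
  } else {
    NULL   # ratios need both groups present
  }

  change_vs_present <- function(df, value_col, by_cols) {
    pres <- df[df$window == present, c(by_cols, value_col)]
    names(pres)[names(pres) == value_col] <- ".present"
    out <- merge(df, pres, by = by_cols)
    out$pct_change <- percent_change(out[[value_col]], out$.present)
    out$.present <- NULL
    out
  }
  group_change <- change_vs_present(group_means, "S_mean",
                                    c("region", "group"))
  species_change <- change_vs_present(sums, "S", c("region", "species"))

  structure(list(sums = sums, group_means = group_means, ratios = ratios,
                 group_change = group_change,
                 species_change = species_change, present = present),
            class = "group_trajectory")
}

#' Rounded report tables from a trajectory
#'
#' @param traj A `group_trajectory`.
#' @return List of data frames with report rounding applied (sums 1
#'   decimal, ratios 3 decimals, percent changes 1 decimal).
#' @export
trajectory_report <- function(traj) {
  sums <- traj$sums; sums$S <- round(sums$S, 1)
  gm <- traj$group_means; gm$S_mean <- round(gm$S_mean, 1)
  ra <- traj$ratios
  if (!is.null(ra)) ra$ratio <- round(ra$ratio, 3)
  gc <- traj$group_change
  gc$S_mean <- round(gc$S_mean, 1); gc$pct_change <- round(gc$pct_change, 1)
  sc <- traj$species_change
  sc$S <- round(sc$S, 1); sc$pct_change <- round(sc$pct_change, 1)
  list(sums = sums, group_means = gm, ratios = ra,
       group_change = gc, species_change = sc)
}
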