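#' Species occurrence set
#'
#' A cleaned set of presence localities for one species.
#'
#' @param species Species name.
#' @param lon,lat Coordinates in WGS84 decimal degrees.
#' @return An object of class `occurrence_set` with a `records` data frame
#'   (`longitude`, `latitude`).
#' @export
occurrence_set <- function(species, lon, lat) {
  stopifnot(length(lon) == length(lat))
  structure(
    list(species = species,
         records = data.frame(longitude = as.numeric(lon),
                              latitude = as.numeric(lat))),
    class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set: %s, %d records\n", x$species, nrow(x$records)))
  invisible(x)
}

#' Clean raw occurrence records
#'
#' Applies the standard cleaning rules for specimen-based occurrence data:
#' rows with unparseable or non-finite coordinates are dropped, records at
#' exactly (0, 0) longitude/latitude are removed as georeferencing errors,
#' exact duplicates (coordinates compared after rounding to 6 decimal
#' places, about 0.1 m) are collapsed to one record, and records outside the
#' study extent are removed. Cleaning is idempotent.
#'
#' @param raw Data frame with columns `species`, `longitude`, `latitude`
#'   (or an `occurrence_set`).
#' @param species Species to retain; defaults to the first species present.
#' @param extent Optional `grid_spec` or list with `west`, `east`, `south`,
#'   `north`: records outside it are removed.
#' @return An `occurrence_set` with attribute `removed`, a named count
#'   vector (`unparseable`, `zero_zero`, `duplicate`, `out_of_extent`).
#' @export
clean_occurrences <- function(raw, species = NULL, extent = NULL) {
  if (inherits(raw, "occurrence_set")) {
    raw <- data.frame(species = raw$species, raw$records)
  }
  raw <- as.data.frame(raw)
  if (is.null(raw$species)) raw$species <- "unknown"
  if (is.null(species)) species <- raw$species[1]
  raw <- raw[raw$species == species, , drop = FALSE]
  lon <- suppressWarnings(as.numeric(raw$longitude))
  lat <- suppressWarnings(as.numeric(raw$latitude))
  removed <- c(unparseable = 0L, zero_zero = 0L, duplicate = 0L,
               out_of_extent = 0L)

  bad <- !is.finite(lon) | !is.finite(lat)
  removed["unparseable"] <- sum(bad)
  lon <- lon[!bad]; lat <- lat[!bad]

  zz <- lon == 0 & lat == 0
  removed["zero_zero"] <- sum(zz)
  lon <- lon[!zz]; lat <- lat[!zz]

  if (!is.null(extent)) {
    oob <- lon < extent$west | lon > extent$east |
      lat < extent$south | lat > extent$north
    removed["out_of_extent"] <- sum(oob)
    lon <- lon[!oob]; lat <- lat[!oob]
  }

  key <- paste(round(lon, 6), round(lat, 6))
  dup <- duplicated(key)
  removed["duplicate"] <- sum(dup)
  out <- occurrence_set(species, lon[!dup], lat[!dup])
  attr(out, "removed") <- removed
  out
}

#' Minimum occurrence count gate
#'
#' Pipeline gate applied after cleaning: a species is modeled only when it
#' retains at least `n_min` occurrence points (inclusive threshold).
#'
#' @param occ An `occurrence_set`.
#' @param n_min Minimum number of records required (default 50).
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
min_occurrence_filter <- function(occ, n_min = 50) {
  nrow(occ$records) >= n_min
}

#' Read/write occurrence CSV
#'
#' CSV schema: header `species,longitude,latitude`, UTF-8.
#'
#' @param path File path.
#' @return For `read_occurrences`, a data frame with the three columns.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("species", "longitude", "latitude")
  if (!all(need %in% names(df)))
    stop("read_occurrences: CSV must have columns ",
         paste(need, collapse = ", "))
  df[need]
}

#' @rdname read_occurrences
#' @param occ An `occurrence_set` or a data frame with the schema columns.
#' @export
write_occurrences <- function(occ, path) {
  df <- if (inherits(occ, "occurrence_set"))
    data.frame(species = occ$species, occ$records) else occ
  utils::write.csv(df[c("species", "longitude", "latitude")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
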