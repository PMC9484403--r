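#' Grid geometry specification
#'
#' Defines the geometry of a regular longitude/latitude raster: extent,
#' cell size, dimensions and the nodata sentinel used on disk. Coordinates
#' are WGS84 decimal degrees; cells are addressed by their centers, row 1
#' being the northernmost row (the ESRI ASCII grid convention).
#'
#' @param west,south,east,north Extent edges in decimal degrees.
#' @param cell_size Cell edge length in decimal degrees (square cells).
#' @param n_rows,n_cols Grid dimensions; derived from the extent and cell
#'   size when omitted.
#' @param nodata Sentinel written to file for missing cells (in memory,
#'   missing cells are `NA`).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(west, south, east, north, cell_size,
                      n_rows = NULL, n_cols = NULL, nodata = -9999) {
  if (east <= west) stop("grid_spec: east must exceed west")
  if (north <= south) stop("grid_spec: north must exceed south")
  if (cell_size <= 0) stop("grid_spec: cell_size must be positive")
  nr <- as.integer(round((north - south) / cell_size))
  nc <- as.integer(round((east - west) / cell_size))
  if (!is.null(n_rows) && n_rows != nr)
    stop("grid_spec: n_rows inconsistent with extent and cell_size")
  if (!is.null(n_cols) && n_cols != nc)
    stop("grid_spec: n_cols inconsistent with extent and cell_size")
  if (abs((north - south) - nr * cell_size) > 1e-6 * cell_size ||
      abs((east - west) - nc * cell_size) > 1e-6 * cell_size)
    stop("grid_spec: extent is not an integer number of cells")
  structure(
    list(n_rows = nr, n_cols = nc, west = west, south = south,
         east = east, north = north, cell_size = cell_size,
         nodata = nodata),
    class = "grid_spec")
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("grid_spec: %d x %d cells, lon [%g, %g], lat [%g, %g], cell %g",
          x$n_rows, x$n_cols, x$west, x$east, x$south, x$north, x$cell_size)
}

#' @export
print.grid_spec <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

same_spec <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$west - b$west) < tol && abs(a$south - b$south) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Raster grid of values on a grid_spec
#'
#' @param values Numeric matrix with `spec$n_rows` rows and `spec$n_cols`
#'   columns; row 1 is the northernmost row. Missing cells are `NA`.
#' @param spec A [grid_spec()].
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, spec) {
  values <- as.matrix(values)
  if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols)
    stop("raster_grid: value dimensions do not match spec")
  storage.mode(values) <- "double"
  structure(list(values = values, spec = spec), class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(format(x$spec), "\n")
  cat(sprintf("  valid cells: %d / %d", length(v), length(x$values)))
  if (length(v))
    cat(sprintf(";  range [%g, %g]", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' Longitudes and latitudes of cell centers
#'
#' @param spec A [grid_spec()].
#' @return For `cell_lons` a length-`n_cols` vector west to east; for
#'   `cell_lats` a length-`n_rows` vector north to south (matching row order).
#' @export
cell_lons <- function(spec) spec$west + (seq_len(spec$n_cols) - 0.5) * spec$cell_size

#' @rdname cell_lons
#' @export
cell_lats <- function(spec) spec$north - (seq_len(spec$n_rows) - 0.5) * spec$cell_size

# row/col of the cell containing each point; NA outside the extent
cell_rowcol <- function(spec, lon, lat) {
  col <- floor((lon - spec$west) / spec$cell_size) + 1
  row <- floor((spec$north - lat) / spec$cell_size) + 1
  # points on the east/north edge belong to the last cell
  col[lon == spec$east] <- spec$n_cols
  row[lat == spec$south] <- spec$n_rows
  bad <- col < 1 | col > spec$n_cols | row < 1 | row > spec$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at point locations
#'
#' @param grid A [raster_grid()].
#' @param lon,lat Point coordinates in decimal degrees.
#' @return Numeric vector of cell values (`NA` outside the extent or at
#'   nodata cells).
#' @export
extract_values <- function(grid, lon, lat) {
  rc <- cell_rowcol(grid$spec, lon, lat)
  out <- rep(NA_real_, length(lon))
  ok <- !is.na(rc[, 1])
  out[ok] <- grid$values[cbind(rc[ok, 1], rc[ok, 2])]
  out
}

#' Read a raster from file
#'
#' Reads a single-band raster in ESRI ASCII grid format (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value` header followed by
#' row-major values north to south). GeoTIFF is not supported in this build:
#' no installed reader handles GeoTIFF georeferencing, and the pipeline's
#' native exchange format is ASCII grid.
#'
#' @param path Path to the file.
#' @param format `"ascii_grid"` (default) or `"geotiff"` (unsupported).
#' @return A [raster_grid()].
#' @export
read_raster <- function(path, format = c("ascii_grid", "geotiff")) {
  format <- match.arg(format)
  if (format == "geotiff")
    stop("read_raster: GeoTIFF is not supported in this build; ",
         "use format = \"ascii_grid\"")
  if (!file.exists(path)) stop("read_raster: file not found: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2 || is.na(suppressWarnings(as.numeric(parts[2]))))
      stop("read_raster: malformed header line ", i, ": ", lines[i])
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  for (f in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[f]]))
      stop("read_raster: header missing required field '", f, "'")
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  n_skip <- if (is.null(hdr$nodata_value)) 5L else 6L
  vals <- scan(path, what = double(), skip = n_skip, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("read_raster: expected ", nr * nc, " values, found ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  spec <- grid_spec(west = hdr$xllcorner, south = hdr$yllcorner,
                    east = hdr$xllcorner + nc * hdr$cellsize,
                    north = hdr$yllcorner + nr * hdr$cellsize,
                    cell_size = hdr$cellsize, nodata = nodata)
  raster_grid(m, spec)
}

#' Write a raster to file
#'
#' Writes ESRI ASCII grid with values at 6 significant digits (the
#' round-trip precision of the format as written here). `NA` cells are
#' written as the spec's nodata sentinel.
#'
#' @param grid A [raster_grid()].
#' @param path Output path.
#' @param format `"ascii_grid"` (default) or `"geotiff"` (unsupported).
#' @param digits Significant digits for cell values.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, format = c("ascii_grid", "geotiff"),
                         digits = 6) {
  format <- match.arg(format)
  if (format == "geotiff")
    stop("write_raster: GeoTIFF is not supported in this build; ",
         "use format = \"ascii_grid\"")
  s <- grid$spec
  hdr <- c(
    sprintf("ncols %d", s$n_cols),
    sprintf("nrows %d", s$n_rows),
    sprintf("xllcorner %.10g", s$west),
    sprintf("yllcorner %.10g", s$south),
    sprintf("cellsize %.10g", s$cell_size),
    sprintf("NODATA_value %.10g", s$nodata))
  m <- grid$values
  m[is.na(m)] <- s$nodata
  body <- apply(m, 1, function(r) paste(signif(r, digits), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Clip a raster to a bounding box
#'
#' Keeps the cells whose centers fall inside the box (inclusive bounds).
#' Cell values and alignment are preserved; no resampling occurs.
#'
#' @param grid A [raster_grid()].
#' @param west,south,east,north Box edges in decimal degrees.
#' @return A [raster_grid()] covering the intersection.
#' @export
clip_extent <- function(grid, west, south, east, north) {
  s <- grid$spec
  lons <- cell_lons(s); lats <- cell_lats(s)
  keep_c <- which(lons >= west & lons <= east)
  keep_r <- which(lats >= south & lats <= north)
  if (!length(keep_c) || !length(keep_r))
    stop("clip_extent: box does not overlap the grid")
  sub <- grid$values[keep_r, keep_c, drop = FALSE]
  new_spec <- grid_spec(
    west  = s$west + (min(keep_c) - 1) * s$cell_size,
    east  = s$west + max(keep_c) * s$cell_size,
    south = s$north - max(keep_r) * s$cell_size,
    north = s$north - (min(keep_r) - 1) * s$cell_size,
    cell_size = s$cell_size, nodata = s$nodata)
  raster_grid(sub, new_spec)
}

#' Mask cells above an elevation cutoff
#'
#' Sets to nodata every cell whose elevation strictly exceeds `cutoff_m`.
#' Used to restrict coastal-species models to low-lying land (default 10 m).
#'
#' @param grid A [raster_grid()] to mask.
#' @param elevation A [raster_grid()] of elevations in meters, on the same
#'   grid geometry.
#' @param cutoff_m Elevation cutoff in meters; cells with elevation
#'   `> cutoff_m` are masked (strict inequality: exactly 10 m is kept).
#' @return The masked [raster_grid()].
#' @export
elevation_mask <- function(grid, elevation, cutoff_m = 10) {
  if (!same_spec(grid$spec, elevation$spec))
    stop("elevation_mask: grid and elevation specs differ")
  v <- grid$values
  v[!is.na(elevation$values) & elevation$values > cutoff_m] <- NA_real_
  v[is.na(elevation$values)] <- NA_real_
  raster_grid(v, grid$spec)
}
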