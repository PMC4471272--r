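# Shared geospatial types: lon/lat grids, raster layers, environment stacks,
# occurrence tables, great-circle distances and point-in-cell extraction.

#' Mean Earth radius (km) used for all great-circle distances
#' @keywords internal
EARTH_RADIUS_KM <- 6371.0088

#' Define a regular lon/lat grid
#'
#' A `grid_spec` describes a north-up, cell-center-registered grid in WGS84
#' decimal degrees.  Row 1 is the northernmost row; cell centers sit at
#' `edge + (i - 0.5) * cell_size`.
#'
#' @param lon_min,lon_max,lat_min,lat_max Extent in decimal degrees.
#' @param cell_size Cell size in degrees (square cells).
#' @return An object of class `grid_spec` with fields `lon_min`, `lon_max`,
#'   `lat_min`, `lat_max`, `cell_size`, `n_rows`, `n_cols`.
#' @examples
#' grid_spec(-82, -69, -7, 11, cell_size = 0.5)
#' @export
grid_spec <- function(lon_min, lon_max, lat_min, lat_max, cell_size) {
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (lon_min >= lon_max) stop("lon_min must be < lon_max")
  if (lat_min >= lat_max) stop("lat_min must be < lat_max")
  n_cols <- as.integer(round((lon_max - lon_min) / cell_size))
  n_rows <- as.integer(round((lat_max - lat_min) / cell_size))
  if (n_cols < 1L || n_rows < 1L)
    stop("degenerate grid: extent smaller than one cell")
  structure(
    list(lon_min = lon_min, lon_max = lon_max,
         lat_min = lat_min, lat_max = lat_max,
         cell_size = cell_size, n_rows = n_rows, n_cols = n_cols),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d rows x %d cols @ %g deg\n",
              x$n_rows, x$n_cols, x$cell_size))
  cat(sprintf("  lon [%g, %g], lat [%g, %g]\n",
              x$lon_min, x$lon_max, x$lat_min, x$lat_max))
  invisible(x)
}

#' Longitudes of cell-column centers / latitudes of cell-row centers
#'
#' @param spec A [grid_spec()].
#' @return Numeric vector of center coordinates.  Latitudes run north to
#'   south to match the row order of raster matrices.
#' @export
cell_lons <- function(spec) {
  spec$lon_min + (seq_len(spec$n_cols) - 0.5) * spec$cell_size
}

#' @rdname cell_lons
#' @export
cell_lats <- function(spec) {
  spec$lat_max - (seq_len(spec$n_rows) - 0.5) * spec$cell_size
}

#' All cell-center coordinates of a grid
#'
#' @param spec A [grid_spec()].
#' @return A data.frame with columns `longitude`, `latitude`, `row`, `col`,
#'   one line per cell in row-major (north-to-south) order.
#' @export
cell_centers <- function(spec) {
  lons <- cell_lons(spec)
  lats <- cell_lats(spec)
  data.frame(
    longitude = rep(lons, times = spec$n_rows),
    latitude  = rep(lats, each = spec$n_cols),
    row = rep(seq_len(spec$n_rows), each = spec$n_cols),
    col = rep(seq_len(spec$n_cols), times = spec$n_rows))
}

#' A single raster layer on a lon/lat grid
#'
#' Values are stored as an `n_rows x n_cols` matrix with row 1 = north;
#' `NA` entries are nodata.
#'
#' @param spec A [grid_spec()].
#' @param values Numeric matrix of dimension `n_rows x n_cols`; `NA` marks
#'   nodata cells.
#' @param name Layer name.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(spec, values, name = "layer") {
  stopifnot(inherits(spec, "grid_spec"))
  values <- as.matrix(values)
  if (!all(dim(values) == c(spec$n_rows, spec$n_cols)))
    stop(sprintf("values must be %d x %d", spec$n_rows, spec$n_cols))
  if (any(!is.finite(values) & !is.na(values)))
    stop("raster values must be finite or NA (nodata)")
  structure(list(spec = spec, values = values, name = as.character(name)),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("raster_grid '%s': %d x %d, %d nodata cells\n", x$name,
              x$spec$n_rows, x$spec$n_cols, sum(is.na(x$values))))
  if (length(v))
    cat(sprintf("  range [%g, %g], mean %g\n", min(v), max(v), mean(v)))
  invisible(x)
}

#' Nodata mask of a raster layer
#' @param grid A [raster_grid()].
#' @return Logical matrix, `TRUE` where the cell is nodata.
#' @export
nodata_mask <- function(grid) is.na(grid$values)

#' Bundle co-registered raster layers into a predictor stack
#'
#' @param layers List of [raster_grid()] objects sharing one [grid_spec()]
#'   and carrying unique names.
#' @return An object of class `env_stack` with fields `spec` and `layers`
#'   (a named list).  The joint nodata mask is the union of the layers'
#'   masks (see [stack_nodata_mask()]).
#' @export
env_stack <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  for (l in layers) stopifnot(inherits(l, "raster_grid"))
  spec <- layers[[1L]]$spec
  for (l in layers)
    if (!identical(unclass(l$spec), unclass(spec)))
      stop("all layers must share one grid_spec")
  nms <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(nms)) stop("layer names must be unique")
  names(layers) <- nms
  structure(list(spec = spec, layers = layers), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack: %d layers on %d x %d grid\n  %s\n",
              length(x$layers), x$spec$n_rows, x$spec$n_cols,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' @rdname nodata_mask
#' @param stack An [env_stack()].
#' @export
stack_nodata_mask <- function(stack) {
  m <- is.na(stack$layers[[1L]]$values)
  for (l in stack$layers[-1L]) m <- m | is.na(l$values)
  m
}

#' Great-circle distance in kilometers
#'
#' Haversine distance on a sphere of radius 6371.0088 km (no projection);
#' computation is delegated to [geosphere::distHaversine()].
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (vectors are
#'   recycled elementwise).
#' @return Distances in km.
#' @examples
#' haversine_km(-75, 4, -75, 5)  # ~111.2 km for one degree of latitude
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  check_coords(lon1, lat1)
  check_coords(lon2, lat2)
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

#' All-pairs great-circle distance matrix in km
#' @param pts Two-column matrix or data.frame of (longitude, latitude).
#' @return Symmetric matrix of distances in km.
#' @keywords internal
pairwise_km <- function(pts) {
  pts <- as.matrix(pts[, 1:2])
  check_coords(pts[, 1], pts[, 2])
  geosphere::distm(pts, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000)) / 1000
}

check_coords <- function(lon, lat) {
  if (anyNA(lon) || anyNA(lat) ||
      any(lon < -180 | lon > 180) || any(lat < -90 | lat > 90))
    stop("invalid coordinates: longitude must be in [-180, 180], ",
         "latitude in [-90, 90], no missing values")
  invisible(TRUE)
}

#' Locate the grid cell containing each point
#'
#' Points on a cell boundary belong to the cell whose center is nearest;
#' exact midpoints go to the higher column (east) and lower row (north)
#' index.
#'
#' @param spec A [grid_spec()].
#' @param lon,lat Point coordinates in decimal degrees.
#' @return A data.frame with integer columns `row`, `col` (row 1 = north).
#' @export
cell_of_point <- function(spec, lon, lat) {
  check_coords(lon, lat)
  inside <- lon >= spec$lon_min & lon <= spec$lon_max &
            lat >= spec$lat_min & lat <= spec$lat_max
  if (!all(inside))
    stop(sprintf("point outside grid extent (first offender index %d)",
                 which(!inside)[1L]))
  col <- floor((lon - spec$lon_min) / spec$cell_size) + 1
  col <- pmin(as.integer(col), spec$n_cols)
  row <- ceiling((spec$lat_max - lat) / spec$cell_size)
  row <- pmax(as.integer(row), 1L)
  data.frame(row = row, col = col)
}

#' Extract predictor values at points
#'
#' Each point is assigned to the grid cell containing it (see
#' [cell_of_point()] for the boundary convention) and the stack's layer
#' values at that cell are returned.
#'
#' @param stack An [env_stack()].
#' @param points Two-column matrix/data.frame of (longitude, latitude), or a
#'   data.frame with `longitude`/`latitude` columns.
#' @return Numeric matrix with one row per point and one column per layer;
#'   attribute `nodata` is a logical vector flagging points that fall in a
#'   joint-nodata cell (their row is `NA`).
#' @export
extract_at_points <- function(stack, points) {
  stopifnot(inherits(stack, "env_stack"))
  pts <- as_lonlat(points)
  rc <- cell_of_point(stack$spec, pts[, 1], pts[, 2])
  idx <- cbind(rc$row, rc$col)
  out <- vapply(stack$layers, function(l) l$values[idx],
                numeric(nrow(idx)))
  out <- matrix(out, nrow = nrow(idx),
                dimnames = list(NULL, names(stack$layers)))
  nod <- stack_nodata_mask(stack)[idx]
  attr(out, "nodata") <- nod
  out
}

# Coerce point input to a two-column (lon, lat) matrix.
as_lonlat <- function(points) {
  if (is.data.frame(points) &&
      all(c("longitude", "latitude") %in% names(points)))
    return(cbind(points$longitude, points$latitude))
  m <- as.matrix(points)
  if (ncol(m) < 2L) stop("points must have two columns (longitude, latitude)")
  m[, 1:2, drop = FALSE]
}

#' Construct an occurrence table
#'
#' Occurrence records are plain data.frames with columns `longitude`,
#' `latitude` and optional effort metadata: `protocol` (one of
#' `stationary`, `traveling`, `area`, `specimen`, `unknown`), `distance_km`
#' (traveling counts only), `area_km2` (area counts only) and `source_id`.
#'
#' @param df Data.frame holding at least `longitude` and `latitude`.
#' @param species Species label stored as an attribute.
#' @return Validated data.frame of class `occurrence_set`.
#' @export
occurrence_set <- function(df, species = "unknown") {
  stopifnot(is.data.frame(df))
  need <- c("longitude", "latitude")
  if (!all(need %in% names(df)))
    stop("occurrence table needs columns 'longitude' and 'latitude'")
  bad <- which(is.na(df$longitude) | is.na(df$latitude) |
               df$longitude < -180 | df$longitude > 180 |
               df$latitude < -90 | df$latitude > 90)
  if (length(bad))
    stop(sprintf("invalid coordinates at row %d", bad[1L]))
  if (is.null(df$protocol)) df$protocol <- rep("unknown", nrow(df))
  ok <- c("stationary", "traveling", "area", "specimen", "unknown")
  badp <- which(!df$protocol %in% ok)
  if (length(badp))
    stop(sprintf("unknown protocol '%s' at row %d",
                 df$protocol[badp[1L]], badp[1L]))
  if (is.null(df$distance_km)) df$distance_km <- rep(NA_real_, nrow(df))
  if (is.null(df$area_km2)) df$area_km2 <- rep(NA_real_, nrow(df))
  if (is.null(df$source_id)) df$source_id <- as.character(seq_len(nrow(df)))
  df <- df[, c("longitude", "latitude", "protocol", "distance_km",
               "area_km2", "source_id")]
  structure(df, species = species,
            class = c("occurrence_set", "data.frame"))
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set: %d records of '%s'\n",
              nrow(x), attr(x, "species")))
  NextMethod()
}
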