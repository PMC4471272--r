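# Raster and point file I/O.
#
# Rasters use the ESRI ASCII grid format (.asc): a plain-text, single-band,
# north-up raster interchange format (header of ncols/nrows/xllcorner/
# yllcorner/cellsize/NODATA_value followed by rows from north to south).
# Points use headered CSV with required longitude/latitude columns.

#' Read / write a raster layer as ESRI ASCII grid
#'
#' @param path File path (`.asc`).
#' @param grid A [raster_grid()].
#' @param name Layer name to attach on read (default: file stem).
#' @param digits Significant digits written (default 10; round-trips
#'   doubles to ~1e-10 relative precision).
#' @return `read_raster` returns a [raster_grid()]; `write_raster` returns
#'   `path` invisibly.
#' @export
read_raster <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7L)
    stop(sprintf("malformed raster '%s': fewer than 7 lines", path))
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(parts) != 2L)
      stop(sprintf("malformed raster header at line %d: '%s'", i, lines[i]))
    val <- suppressWarnings(as.numeric(parts[2L]))
    if (is.na(val))
      stop(sprintf("non-numeric raster header value at line %d: '%s'",
                   i, lines[i]))
    hdr[[tolower(parts[1L])]] <- val
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop(sprintf("raster header missing field(s): %s",
                 paste(setdiff(need, names(hdr)), collapse = ", ")))
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr)
    stop(sprintf("raster body has %d rows, header says %d",
                 length(body), nr))
  vals <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1L]]))
    if (length(row) != nc)
      stop(sprintf("raster data row %d has %d values, expected %d",
                   i, length(row), nc))
    if (anyNA(row))
      stop(sprintf("non-numeric value in raster data row %d", i))
    vals[i, ] <- row
  }
  vals[vals == hdr$nodata_value] <- NA_real_
  spec <- grid_spec(hdr$xllcorner, hdr$xllcorner + nc * hdr$cellsize,
                    hdr$yllcorner, hdr$yllcorner + nr * hdr$cellsize,
                    hdr$cellsize)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  raster_grid(spec, vals, name = name)
}

#' @rdname read_raster
#' @export
write_raster <- function(grid, path, digits = 10) {
  stopifnot(inherits(grid, "raster_grid"))
  s <- grid$spec
  nodata <- -9999
  v <- grid$values
  if (any(v == nodata, na.rm = TRUE))
    stop("raster contains the nodata sentinel -9999 as a real value")
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", s$n_cols),
           sprintf("nrows %d", s$n_rows),
           sprintf("xllcorner %.10g", s$lon_min),
           sprintf("yllcorner %.10g", s$lat_min),
           sprintf("cellsize %.10g", s$cell_size),
           sprintf("NODATA_value %d", nodata))
  rows <- apply(v, 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write an environment stack as one ASCII grid per layer
#'
#' @param stack An [env_stack()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "env_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(names(stack$layers), ".asc"))
  for (i in seq_along(stack$layers))
    write_raster(stack$layers[[i]], paths[i])
  invisible(paths)
}

#' @rdname write_stack
#' @param paths Character vector of `.asc` files to read as one stack.
#' @export
read_stack <- function(paths) {
  env_stack(lapply(paths, read_raster))
}

#' Read / write occurrence points as CSV
#'
#' The CSV must carry `longitude` and `latitude` columns (any order);
#' `protocol`, `distance_km`, `area_km2` and `source_id` are optional.
#' Rows with out-of-domain coordinates are rejected with their row number.
#'
#' @param path CSV file path.
#' @param set An [occurrence_set()].
#' @param species Species label to attach on read.
#' @return `read_points` returns an [occurrence_set()]; `write_points`
#'   returns `path` invisibly.
#' @export
read_points <- function(path, species = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("longitude", "latitude") %in% names(df)))
    stop(sprintf("'%s' lacks required columns longitude/latitude", path))
  if (!is.numeric(df$longitude) || !is.numeric(df$latitude))
    stop(sprintf("'%s': longitude/latitude must be numeric", path))
  if (is.null(species)) {
    species <- if ("species" %in% names(df) && nrow(df))
      df$species[1L] else sub("\\.[^.]*$", "", basename(path))
  }
  tryCatch(occurrence_set(df, species = species),
           error = function(e)
             stop(sprintf("'%s': %s", path, conditionMessage(e)),
                  call. = FALSE))
}

#' @rdname read_points
#' @export
write_points <- function(set, path) {
  df <- as.data.frame(set)
  df$species <- attr(set, "species")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
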