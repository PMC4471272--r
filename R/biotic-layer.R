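# Distance-buffered binary resource layer: a cell is "resource present"
# when its center lies within a fixed great-circle radius of any known
# resource-species locality.

#' Rasterize resource points into a binary buffered layer
#'
#' Cell value is 1 iff the haversine distance from the cell center to the
#' nearest source point is less than or equal to `radius_km` (inclusive,
#' on cell centers); 0 otherwise.  Cells flagged nodata by `nodata` stay
#' nodata.
#'
#' @param points An [occurrence_set()] (or lon/lat data.frame) of
#'   resource-species localities; may be empty (all-zero layer).
#' @param radius_km Buffer radius in km (default 20).
#' @param spec A [grid_spec()] defining the target grid.
#' @param nodata Optional logical matrix marking nodata cells.
#' @param name Layer name (default `"resource"`).
#' @return A binary [raster_grid()]; attribute `radius_km` records the
#'   buffer radius.
#' @export
rasterize_buffer <- function(points, radius_km = 20, spec,
                             nodata = NULL, name = "resource") {
  stopifnot(inherits(spec, "grid_spec"), radius_km > 0)
  df <- as.data.frame(points)
  v <- matrix(0, spec$n_rows, spec$n_cols)
  if (nrow(df) > 0L) {
    check_coords(df$longitude, df$latitude)
    centers <- cell_centers(spec)          # row-major order
    pts <- cbind(df$longitude, df$latitude)
    near <- rep(FALSE, nrow(centers))
    # chunked all-pairs haversine: cells x points
    chunk <- 4096L
    for (start in seq(1L, nrow(centers), by = chunk)) {
      idx <- start:min(start + chunk - 1L, nrow(centers))
      D <- geosphere::distm(
        cbind(centers$longitude[idx], centers$latitude[idx]), pts,
        fun = function(p1, p2)
          geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000))
      near[idx] <- apply(D, 1L, min) <= radius_km * 1000
    }
    v <- matrix(as.numeric(near), spec$n_rows, spec$n_cols, byrow = TRUE)
  }
  if (!is.null(nodata)) v[nodata] <- NA
  out <- raster_grid(spec, v, name = name)
  attr(out, "radius_km") <- radius_km
  out
}
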