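# Occurrence preparation: effort-based record acceptance, 1-km spatial
# thinning, train/test partitioning and background (pseudo-absence)
# sampling.

#' Effort-based record acceptance
#'
#' A record is accepted if it is a stationary count, an exhaustive area
#' count covering strictly less than `max_area_km2`, a traveling count
#' covering strictly less than `max_distance_km`, or a specimen record.
#' All other records are rejected with a machine-readable reason code.
#' Thresholds are strict (`<`): a traveling count of exactly 5 km or an
#' area count of exactly 1 km^2 is rejected.
#'
#' @param records An [occurrence_set()] or data.frame with `protocol`,
#'   `distance_km`, `area_km2` columns.
#' @param max_distance_km,max_area_km2 Strict upper effort limits.
#' @return A data.frame with logical `accept` and character `reason`
#'   (one of `ok`, `distance_too_long`, `area_too_large`,
#'   `missing_effort`, `unsupported_protocol`), one row per record.
#' @export
filter_effort <- function(records, max_distance_km = 5,
                          max_area_km2 = 1) {
  protocol <- records$protocol
  if (is.null(protocol)) protocol <- rep("unknown", nrow(records))
  dist <- if (is.null(records$distance_km)) rep(NA_real_, nrow(records))
          else records$distance_km
  area <- if (is.null(records$area_km2)) rep(NA_real_, nrow(records))
          else records$area_km2
  reason <- rep("unsupported_protocol", length(protocol))
  reason[protocol %in% c("stationary", "specimen")] <- "ok"
  tr <- protocol == "traveling"
  reason[tr & is.na(dist)] <- "missing_effort"
  reason[tr & !is.na(dist) & dist < max_distance_km] <- "ok"
  reason[tr & !is.na(dist) & dist >= max_distance_km] <- "distance_too_long"
  ar <- protocol == "area"
  reason[ar & is.na(area)] <- "missing_effort"
  reason[ar & !is.na(area) & area < max_area_km2] <- "ok"
  reason[ar & !is.na(area) & area >= max_area_km2] <- "area_too_large"
  data.frame(accept = reason == "ok", reason = reason)
}

#' Keep only records passing the effort filter
#'
#' @inheritParams filter_effort
#' @return The accepted subset as an [occurrence_set()], with attribute
#'   `filter_log` holding the per-record decision table.
#' @export
apply_effort_filter <- function(records, max_distance_km = 5,
                                max_area_km2 = 1) {
  dec <- filter_effort(records, max_distance_km, max_area_km2)
  out <- occurrence_set(as.data.frame(records)[dec$accept, , drop = FALSE],
                        species = attr(records, "species") %||% "unknown")
  attr(out, "filter_log") <- dec
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spatial thinning to a minimum nearest-neighbor distance
#'
#' Randomized greedy elimination: while any pair of retained records lies
#' closer than `min_km` (great-circle), one record is removed uniformly at
#' random from those with the largest number of sub-threshold neighbors.
#' The procedure is repeated `n_reps` times and the largest surviving set
#' is returned (ties broken by the earliest repetition).  The output is
#' maximal: no removed record can be restored without violating the
#' constraint.
#'
#' @param points An [occurrence_set()] (or lon/lat data.frame).
#' @param min_km Minimum pairwise distance in km (violation is
#'   `distance < min_km`).
#' @param n_reps Number of randomized repetitions (default 100).
#' @param seed Integer seed.
#' @return Thinned [occurrence_set()]; attribute `n_retained_per_rep`
#'   gives the retained count of every repetition.
#' @export
thin <- function(points, min_km = 1.0, n_reps = 100, seed = 1) {
  stopifnot(min_km > 0, n_reps >= 1)
  df <- as.data.frame(points)
  n <- nrow(df)
  if (n == 0L) return(points)
  D <- pairwise_km(cbind(df$longitude, df$latitude))
  viol <- D < min_km
  diag(viol) <- FALSE
  best <- NULL
  per_rep <- integer(n_reps)
  with_local_seed(seed, {
    for (r in seq_len(n_reps)) {
      alive <- rep(TRUE, n)
      counts <- rowSums(viol)
      while (any(counts[alive] > 0)) {
        worst <- which(alive & counts == max(counts[alive]))
        drop <- if (length(worst) == 1L) worst else
          worst[sample.int(length(worst), 1L)]
        alive[drop] <- FALSE
        nb <- which(viol[drop, ] & alive)
        counts[nb] <- counts[nb] - 1L
        counts[drop] <- 0L
      }
      # restoration pass: removed records that no longer conflict with
      # any survivor are re-added, making the result maximal
      rem <- which(!alive)
      for (p in rem[sample.int(length(rem))]) {
        if (!any(viol[p, ] & alive)) alive[p] <- TRUE
      }
      per_rep[r] <- sum(alive)
      if (is.null(best) || sum(alive) > sum(best)) best <- alive
    }
  })
  out <- occurrence_set(df[best, , drop = FALSE],
                        species = attr(points, "species") %||% "unknown")
  attr(out, "n_retained_per_rep") <- per_rep
  out
}

#' Random train/test partition of occurrence records
#'
#' The test set holds `floor(test_fraction * n)` records drawn uniformly
#' without replacement; the remainder trains the model.
#'
#' @param points An [occurrence_set()].
#' @param test_fraction Fraction withheld for testing (default 1/4).
#' @param seed Integer seed.
#' @return List with `train` and `test` [occurrence_set()]s.
#' @export
partition <- function(points, test_fraction = 0.25, seed = 1) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  df <- as.data.frame(points)
  n <- nrow(df)
  if (n < 2L) stop("need at least 2 records to partition")
  n_test <- floor(test_fraction * n)
  sp <- attr(points, "species") %||% "unknown"
  with_local_seed(seed, {
    test_idx <- sample.int(n, n_test)
    list(train = occurrence_set(df[-test_idx, , drop = FALSE], species = sp),
         test = occurrence_set(df[test_idx, , drop = FALSE], species = sp))
  })
}

#' Sample background (pseudo-absence) points
#'
#' Cells are drawn uniformly (with replacement) from the stack's
#' non-nodata cells; each point sits at its cell center.  Presence cells
#' are not excluded.
#'
#' @param stack An [env_stack()].
#' @param n Number of background points (default 250).
#' @param seed Integer seed.
#' @return Data.frame with `longitude` and `latitude` columns.
#' @export
sample_background <- function(stack, n = 250, seed = 1) {
  stopifnot(inherits(stack, "env_stack"), n >= 1)
  centers <- cell_centers(stack$spec)
  valid <- !as.vector(t(stack_nodata_mask(stack)))  # row-major order
  if (sum(valid) < 1L) stop("no valid (non-nodata) cells to sample from")
  pool <- which(valid)
  with_local_seed(seed, {
    idx <- pool[sample.int(length(pool), n, replace = TRUE)]
    data.frame(longitude = centers$longitude[idx],
               latitude = centers$latitude[idx])
  })
}

#' One-call data preparation
#'
#' Applies the effort filter, thins to `min_km`, partitions into
#' train/test, and samples background points -- the full preparation
#' pathway in one step.
#'
#' @inheritParams thin
#' @inheritParams partition
#' @param stack An [env_stack()] for background sampling.
#' @param n_background Number of pseudo-absence points.
#' @param thin_reps Thinning repetitions.
#' @param seed Integer seed (stages use `seed`, `seed + 1`, `seed + 2`).
#' @return List of class `partitioned_data` with `thinned`, `train`,
#'   `test`, `background` and a `counts` vector tracking records through
#'   each stage.
#' @export
prepare_data <- function(points, stack, min_km = 1.0, test_fraction = 0.25,
                         n_background = 250, thin_reps = 100, seed = 1) {
  filtered <- apply_effort_filter(points)
  thinned <- thin(filtered, min_km = min_km, n_reps = thin_reps, seed = seed)
  parts <- partition(thinned, test_fraction = test_fraction, seed = seed + 1)
  bg <- sample_background(stack, n = n_background, seed = seed + 2)
  structure(list(
    thinned = thinned, train = parts$train, test = parts$test,
    background = bg,
    counts = c(input = nrow(points), accepted = nrow(filtered),
               thinned = nrow(thinned), train = nrow(parts$train),
               test = nrow(parts$test), background = nrow(bg))),
    class = "partitioned_data")
}

#' @export
print.partitioned_data <- function(x, ...) {
  cat("partitioned_data:\n")
  print(x$counts)
  invisible(x)
}
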