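# Synthetic landscapes: smooth climate-like predictor stacks, a resource
# species' range mask, a true suitability surface with tunable biotic
# dependence, and occurrence records sampled from it.  Every downstream
# stage of the pipeline can be exercised on these without any downloads.

# Run code under a temporary RNG state; the caller's stream is untouched.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Separable Gaussian blur with edge renormalization (reflect-free: the
# kernel is truncated and re-normalized at the borders).
gaussian_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  smooth_1d <- function(n) {
    # n x n band matrix, rows renormalized so constants are preserved
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1L, i - half):min(n, i + half)
      K[i, j] <- k[j - i + half + 1L]
    }
    K / rowSums(K)
  }
  Kr <- smooth_1d(nrow(mat))
  Kc <- smooth_1d(ncol(mat))
  Kr %*% mat %*% t(Kc)
}

# Mean-0, sd-1 standardization over non-NA cells.
standardize_grid <- function(v) {
  ok <- !is.na(v)
  mu <- mean(v[ok]); sd <- stats::sd(v[ok])
  if (!is.finite(sd) || sd == 0) stop("degenerate (constant) field")
  v[ok] <- (v[ok] - mu) / sd
  v
}

#' Generate a stack of smooth, climate-like predictor fields
#'
#' Each layer is a random latitudinal/longitudinal gradient plus spatially
#' smoothed Gaussian noise, standardized to mean 0 and sd 1 over valid
#' cells.  Layers are mutually independent but each is spatially
#' autocorrelated with correlation length set by `smoothness`.
#'
#' @param spec A [grid_spec()].
#' @param n_layers Number of layers (default 19, the size of a standard
#'   bioclimatic variable set).
#' @param smoothness Gaussian-blur sigma in cells (>= 1); larger values give
#'   smoother fields.
#' @param seed Integer seed; the same seed reproduces the stack exactly.
#' @return An [env_stack()] with layers named `clim01`, `clim02`, ...
#' @export
generate_climate_stack <- function(spec, n_layers = 19, smoothness = 8,
                                   seed = 1) {
  stopifnot(inherits(spec, "grid_spec"))
  if (n_layers < 1) stop("n_layers must be >= 1")
  if (smoothness < 1) stop("smoothness must be >= 1")
  nr <- spec$n_rows; nc <- spec$n_cols
  lat_grad <- matrix(rep(seq(1, -1, length.out = nr), nc), nr, nc)
  lon_grad <- matrix(rep(seq(-1, 1, length.out = nc), each = nr), nr, nc)
  with_local_seed(seed, {
    layers <- lapply(seq_len(n_layers), function(i) {
      g <- stats::runif(2, -1, 1)
      noise <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                               smoothness)
      v <- g[1] * lat_grad + g[2] * lon_grad + standardize_grid(noise)
      raster_grid(spec, standardize_grid(v),
                  name = sprintf("clim%02d", i))
    })
    env_stack(layers)
  })
}

#' Generate a resource species' range mask
#'
#' The range is the intersection of a smooth latent field exceeding a
#' threshold with a hard latitudinal cut (cells strictly north of
#' `lat_cut`).  The latent field mixes the leading stack layers with
#' smoothed noise, so the resource range tracks climate; the latitudinal
#' cut then creates a region of cells *south* of the cut whose latent
#' climate score is as good as the occupied range -- the analog of
#' climatically suitable but resource-free terrain beyond a range margin.
#'
#' @param spec A [grid_spec()].
#' @param stack The [env_stack()] the latent field borrows signal from.
#' @param lat_cut Latitude (degrees) of the hard southern range edge.
#' @param threshold Cutoff on the standardized latent field (mask requires
#'   `latent > threshold`); `-Inf` keeps every cell north of `lat_cut`.
#'   Ignored when `target_cells` is given.
#' @param seed Integer seed.
#' @param n_signal How many leading layers feed the latent field.
#' @param require_free_region If `TRUE` (default), it is an error when no
#'   cell south of `lat_cut` has a latent score above the within-range
#'   median; [synthetic_truth()] disables this and derives its own
#'   overprediction-prone region from the focal species' suitability.
#' @param target_cells If non-`NULL` (default 700), the threshold is set
#'   to the latent value leaving this many occupied cells north of
#'   `lat_cut`, fixing the range area across seeds (700 cells at 0.1
#'   degrees is roughly 6e4 km^2, a compact montane-endemic range).
#' @return A binary [raster_grid()] (1 = resource present) with attribute
#'   `free_region`: a two-column matrix of (row, col) indices of cells
#'   south of `lat_cut` whose latent score exceeds the within-range median
#'   -- the suitable-but-resource-free region.
#' @export
generate_resource_range <- function(spec, stack, lat_cut = 0,
                                    threshold = 1.6, seed = 1,
                                    n_signal = 3, target_cells = 700,
                                    require_free_region = TRUE) {
  stopifnot(inherits(spec, "grid_spec"), inherits(stack, "env_stack"))
  if (lat_cut < spec$lat_min || lat_cut > spec$lat_max)
    stop("lat_cut must lie inside the grid extent")
  k <- min(n_signal, length(stack$layers))
  clim <- Reduce(`+`, lapply(stack$layers[seq_len(k)],
                             function(l) l$values)) / k
  # The resource's own niche axes vary at a finer spatial scale (sigma 4
  # cells) than the coarse climate fields, so its range is not a function
  # of the climate stack -- a patchy, partly edaphic range.
  latent <- with_local_seed(seed, {
    noise <- gaussian_smooth(matrix(stats::rnorm(spec$n_rows * spec$n_cols),
                                    spec$n_rows, spec$n_cols), 4)
    standardize_grid(0.4 * standardize_grid(clim) +
                     0.6 * standardize_grid(noise))
  })
  lat <- matrix(rep(cell_lats(spec), spec$n_cols), spec$n_rows, spec$n_cols)
  north <- lat > lat_cut
  if (!is.null(target_cells)) {
    pool <- latent[north & !stack_nodata_mask(stack)]
    if (target_cells >= length(pool))
      threshold <- -Inf
    else
      threshold <- sort(pool, decreasing = TRUE)[target_cells + 1L]
  }
  mask <- (latent > threshold) & north
  mask_num <- mask + 0
  mask_num[stack_nodata_mask(stack)] <- NA
  if (!any(mask, na.rm = TRUE))
    stop("resource mask is empty; raise the seed or lower the threshold")
  med <- stats::median(latent[mask])
  free <- which(!north & latent > med & !is.na(mask_num), arr.ind = TRUE)
  if (nrow(free) == 0L && lat_cut > spec$lat_min && require_free_region)
    stop("no suitable-but-resource-free cells south of lat_cut; ",
         "re-seed or lower the threshold")
  out <- raster_grid(spec, mask_num, name = "resource")
  attr(out, "free_region") <- free
  out
}

#' True habitat suitability with tunable biotic dependence
#'
#' The abiotic part is a logistic linear-quadratic function of the stack
#' layers; the biotic part multiplies it by `delta * mask + (1 - delta)`,
#' so `delta = 0` means suitability ignores the resource and `delta = 1`
#' means suitability is zero wherever the resource is absent.
#'
#' @param stack An [env_stack()].
#' @param resource_mask Binary [raster_grid()] (from
#'   [generate_resource_range()]).
#' @param coefficients List with `intercept` (scalar), `linear` and
#'   `quadratic` (numeric vectors, one entry per layer; zero = no signal).
#' @param delta Biotic dependence in `[0, 1]`.
#' @return A [raster_grid()] of suitabilities in `[0, 1]`.
#' @export
true_suitability <- function(stack, resource_mask, coefficients, delta) {
  stopifnot(inherits(stack, "env_stack"),
            inherits(resource_mask, "raster_grid"),
            delta >= 0, delta <= 1)
  p <- length(stack$layers)
  a <- coefficients$linear
  b <- coefficients$quadratic
  if (length(a) != p || length(b) != p)
    stop("coefficients$linear and $quadratic must have one entry per layer")
  eta <- matrix(coefficients$intercept, stack$spec$n_rows, stack$spec$n_cols)
  for (i in seq_len(p)) {
    x <- stack$layers[[i]]$values
    eta <- eta + a[i] * x + b[i] * x^2
  }
  s <- stats::plogis(eta) * (delta * resource_mask$values + (1 - delta))
  raster_grid(stack$spec, s, name = "true_suitability")
}

#' Sample presence-only occurrence records from a suitability surface
#'
#' Cells are drawn (with replacement) with probability proportional to
#' suitability; each draw is jittered uniformly within its cell so that
#' sub-kilometer thinning remains meaningful on coarse grids.  Effort
#' metadata are assigned from a protocol mix so the record-acceptance
#' filter is exercised: traveling distances are drawn uniform on
#' `[0, 8]` km and survey areas uniform on `[0, 2]` km^2, so a share of
#' records fails the strict `< 5` km / `< 1` km^2 rules.
#'
#' @param suitability A [raster_grid()] with nonnegative values.
#' @param n Number of records.
#' @param seed Integer seed.
#' @param protocol_mix Named probabilities over
#'   `stationary`/`traveling`/`area`/`specimen`.
#' @param species Species label for the output.
#' @param n_sites If non-`NULL`, records cluster at this many observation
#'   sites (sites drawn from the suitability surface; each record then
#'   falls within `site_radius_km` of its site) -- emulating the strong
#'   site fidelity of citizen-science archives, where many checklists
#'   repeat a few accessible localities and sub-kilometer thinning
#'   collapses the data to roughly one record per site.  `NULL` (default)
#'   gives independent cell draws.
#' @param site_radius_km Within-site scatter radius in km.
#' @return An [occurrence_set()] of `n` records.
#' @export
sample_occurrences <- function(suitability, n = 319, seed = 1,
                               protocol_mix = c(stationary = 0.4,
                                                traveling = 0.3,
                                                area = 0.2,
                                                specimen = 0.1),
                               species = "synthetic-focal",
                               n_sites = NULL, site_radius_km = 0.3) {
  stopifnot(inherits(suitability, "raster_grid"), n >= 1)
  s <- suitability$values
  w <- as.vector(t(s))          # row-major: matches cell_centers() order
  w[is.na(w)] <- 0
  if (all(w <= 0)) stop("suitability has no positive mass; cannot sample")
  spec <- suitability$spec
  centers <- cell_centers(spec)
  with_local_seed(seed, {
    half <- spec$cell_size / 2
    if (is.null(n_sites)) {
      idx <- sample.int(length(w), n, replace = TRUE, prob = w)
      lon <- centers$longitude[idx] + stats::runif(n, -half, half)
      lat <- centers$latitude[idx] + stats::runif(n, -half, half)
    } else {
      # site points keep a margin inside their cell so the within-site
      # scatter cannot cross into a neighboring cell
      margin <- min(half * 0.5, site_radius_km * 2 / 111.195)
      site_cell <- sample.int(length(w), n_sites, replace = TRUE, prob = w)
      site_lon <- centers$longitude[site_cell] +
        stats::runif(n_sites, -(half - margin), half - margin)
      site_lat <- centers$latitude[site_cell] +
        stats::runif(n_sites, -(half - margin), half - margin)
      site_of <- c(seq_len(min(n_sites, n)),
                   if (n > n_sites)
                     sample.int(n_sites, n - n_sites, replace = TRUE))
      r <- site_radius_km * sqrt(stats::runif(n))
      ang <- stats::runif(n, 0, 2 * pi)
      lat <- site_lat[site_of] + r * cos(ang) / 111.195
      lon <- site_lon[site_of] + r * sin(ang) /
        (111.195 * cos(site_lat[site_of] * pi / 180))
      idx <- site_cell[site_of]
    }
    protocol <- sample(names(protocol_mix), n, replace = TRUE,
                       prob = protocol_mix)
    distance_km <- ifelse(protocol == "traveling",
                          stats::runif(n, 0, 8), NA_real_)
    area_km2 <- ifelse(protocol == "area", stats::runif(n, 0, 2), NA_real_)
    occurrence_set(data.frame(
      longitude = lon, latitude = lat, protocol = protocol,
      distance_km = distance_km, area_km2 = area_km2,
      source_id = sprintf("syn%04d", seq_len(n))), species = species)
  })
}

#' Sample resource-species point records from a range mask
#'
#' Emulates an expert-curated herbarium/survey archive: records carry
#' `specimen` protocol and, by default (`mode = "spread"`), are placed by
#' farthest-point sampling over the occupied cells, the way a curated
#' collection database covers a species' whole range rather than
#' clustering -- so a modest number of records with a fixed buffer tiles
#' the range.  `mode = "uniform"` instead draws occupied cells uniformly
#' at random (with replacement).  Points are jittered within their cell.
#'
#' @param resource_mask Binary [raster_grid()].
#' @param n Number of records.
#' @param seed Integer seed.
#' @param mode `"spread"` (farthest-point, default) or `"uniform"`.
#' @return An [occurrence_set()].
#' @export
sample_resource_points <- function(resource_mask, n = 117, seed = 1,
                                   mode = c("spread", "uniform")) {
  mode <- match.arg(mode)
  if (mode == "uniform") {
    m <- raster_grid(resource_mask$spec, resource_mask$values, name = "w")
    return(sample_occurrences(m, n = n, seed = seed,
                              protocol_mix = c(specimen = 1),
                              species = "synthetic-resource"))
  }
  spec <- resource_mask$spec
  occ_cells <- which(t(resource_mask$values) == 1)  # row-major indices
  if (length(occ_cells) == 0L) stop("resource mask has no occupied cells")
  centers <- cell_centers(spec)
  lon_c <- centers$longitude[occ_cells]
  lat_c <- centers$latitude[occ_cells]
  with_local_seed(seed, {
    k <- min(n, length(occ_cells))
    chosen <- integer(k)
    chosen[1L] <- sample.int(length(occ_cells), 1L)
    # squared planar degree distance (latitude-corrected) is enough to
    # rank candidates for spreading
    coslat <- cos(mean(lat_c) * pi / 180)
    d2 <- ((lon_c - lon_c[chosen[1L]]) * coslat)^2 +
      (lat_c - lat_c[chosen[1L]])^2
    if (k > 1L) for (i in 2:k) {
      chosen[i] <- which.max(d2)
      d2 <- pmin(d2, ((lon_c - lon_c[chosen[i]]) * coslat)^2 +
                   (lat_c - lat_c[chosen[i]])^2)
    }
    idx <- occ_cells[chosen]
    if (n > k)    # more records than occupied cells: duplicates allowed
      idx <- c(idx, occ_cells[sample.int(length(occ_cells), n - k,
                                         replace = TRUE)])
    half <- spec$cell_size / 2
    occurrence_set(data.frame(
      longitude = centers$longitude[idx] + stats::runif(n, -half, half),
      latitude = centers$latitude[idx] + stats::runif(n, -half, half),
      protocol = "specimen", distance_km = NA_real_, area_km2 = NA_real_,
      source_id = sprintf("syn-res-%04d", seq_len(n))),
      species = "synthetic-resource")
  })
}

#' Generate a complete synthetic ground truth
#'
#' Convenience wrapper tying together [generate_climate_stack()],
#' [generate_resource_range()] and [true_suitability()].  By default 19
#' layers are generated but only the first `n_signal = 3` carry true
#' signal, so regularization and the variable-importance diagnostics are
#' exercised against noise predictors.
#'
#' @param spec A [grid_spec()]; default is a 0.1-degree grid over
#'   82W--69W, 7S--11N (a northern-Andes-like window).
#' @param n_layers,smoothness Passed to [generate_climate_stack()].
#' @param n_signal Number of leading layers with nonzero true
#'   coefficients.
#' @param delta Biotic dependence of the truth (see [true_suitability()]).
#' @param lat_cut,threshold,target_cells Passed to
#'   [generate_resource_range()].
#' @param coefficients Optional coefficient list; the default puts
#'   moderate linear terms (1.0, -0.7, 0.5) and concave quadratic terms
#'   (-0.6, -0.4, -0.2) on the signal layers with intercept 0 -- a broad,
#'   unimodal climate envelope, so that under `delta = 1` the range is
#'   limited chiefly by the resource, not by climate.
#' @param seed Integer seed controlling every stochastic element.
#' @return A list of class `synthetic_truth` with elements `stack`,
#'   `resource_mask`, `suitability`, `abiotic_suitability` (the climate
#'   part alone), `free_region`, `free_region_south`, `coefficients`,
#'   `delta`, `seed`.  `free_region` indexes the resource-free cells
#'   whose abiotic suitability exceeds the within-range median -- the
#'   cells a climate-only model is prone to overpredict; its
#'   `free_region_south` subset (south of `lat_cut`) is the analog of
#'   suitable terrain beyond the hard range margin and is guaranteed
#'   nonempty.
#' @export
synthetic_truth <- function(spec = NULL, n_layers = 19, smoothness = 8,
                            n_signal = 3, delta = 1, lat_cut = 0,
                            threshold = 1.6, target_cells = 700,
                            coefficients = NULL, seed = 1) {
  if (is.null(spec))
    spec <- grid_spec(-82, -69, -7, 11, cell_size = 0.1)
  if (is.null(coefficients)) {
    a <- b <- numeric(n_layers)
    k <- min(n_signal, n_layers)
    a[seq_len(k)] <- c(1.0, -0.7, 0.5)[seq_len(k)]
    b[seq_len(k)] <- c(-0.6, -0.4, -0.2)[seq_len(k)]
    coefficients <- list(intercept = 0, linear = a, quadratic = b)
  }
  stack <- generate_climate_stack(spec, n_layers, smoothness, seed = seed)
  mask <- generate_resource_range(spec, stack, lat_cut = lat_cut,
                                  threshold = threshold, seed = seed + 1,
                                  n_signal = n_signal,
                                  target_cells = target_cells,
                                  require_free_region = FALSE)
  suit <- true_suitability(stack, mask, coefficients, delta)
  clim_suit <- true_suitability(stack, mask, coefficients, 0)
  clim_suit$name <- "abiotic_suitability"
  occupied <- !is.na(mask$values) & mask$values == 1
  med <- stats::median(clim_suit$values[occupied])
  free_cells <- !is.na(mask$values) & mask$values == 0 &
    clim_suit$values > med
  free <- which(free_cells, arr.ind = TRUE)
  lat_of_row <- cell_lats(spec)
  free_south <- free[lat_of_row[free[, 1]] <= lat_cut, , drop = FALSE]
  if (nrow(free_south) == 0L && lat_cut > spec$lat_min)
    warning("no climatically suitable, resource-free cells south of ",
            "lat_cut for this seed", call. = FALSE)
  structure(list(stack = stack, resource_mask = mask, suitability = suit,
                 abiotic_suitability = clim_suit,
                 free_region = free, free_region_south = free_south,
                 coefficients = coefficients, delta = delta, seed = seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic_truth: %d layers, delta = %g, %d resource cells, %d free cells\n",
    length(x$stack$layers), x$delta,
    sum(x$resource_mask$values == 1, na.rm = TRUE), nrow(x$free_region)))
  invisible(x)
}
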