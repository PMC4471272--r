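# End-to-end three-model comparison: abiotic (climate-only), biotic-only
# (resource layer only) and abiotic+biotic models fitted on one shared
# partition and background, evaluated with the six-index suite, with
# table-style summaries, suitability maps and an overprediction map.

#' Default configuration for the synthetic comparison experiment
#'
#' The documented study conditions: a 0.1-degree grid over 82W--69W,
#' 7S--11N; 19 climate-like layers of which 3 carry true signal; a
#' resource range cut at the equator (the suitable-but-resource-free
#' analog sits south of it); 319 sampled focal records, 117 resource
#' records, 1-km thinning, one-quarter test holdout, 250 background
#' points, a 20-km resource buffer, and default regularization.
#'
#' @param delta Biotic dependence of the generating truth (1 = fully
#'   resource-limited, 0 = climate-only truth).
#' @param seed Integer master seed.
#' @param cell_size Grid resolution in degrees.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(delta = 1, seed = 1, cell_size = 0.1) {
  structure(list(
    extent = c(lon_min = -82, lon_max = -69, lat_min = -7, lat_max = 11),
    cell_size = cell_size,
    n_layers = 19, n_signal = 3, smoothness = 8,
    delta = delta, lat_cut = 0, threshold = 1.6, target_cells = 700,
    n_occurrences = 319, n_sites = 120, n_resource = 117,
    min_km = 1, thin_reps = 100, test_fraction = 0.25,
    n_background = 250, radius_km = 20,
    beta_multiplier = 1, threshold_grid = default_threshold_grid(),
    n_perm = 5, seed = seed),
    class = "run_config")
}

# Predictor matrices for one model variant at given points.
variant_stack <- function(stack, biotic, which) {
  switch(which,
    abiotic = stack,
    biotic_only = env_stack(list(biotic)),
    abiotic_plus_biotic = env_stack(c(stack$layers, list(biotic))))
}

#' Run the three-model comparison on a synthetic landscape
#'
#' Generates the ground truth, samples and prepares occurrence data (one
#' effort filter, one thinning, one partition, one background draw shared
#' by all three model variants), builds the buffered resource layer, fits
#' the abiotic, biotic-only and abiotic+biotic models, and evaluates each
#' with the six-index suite on the same test presences and
#' pseudo-absences.
#'
#' @param config A [default_config()] list.
#' @param make_maps If `TRUE` (default) also predict continuous
#'   suitability over the whole grid and binarize it at each model's
#'   max-kappa threshold (needed for [overprediction_map()]).
#' @return Object of class `comparison_report`: per model a list with
#'   `model`, `evaluation` ([evaluate_predictions()]),
#'   `contribution` ([contribution_table()]), and (with maps)
#'   `suitability` and `binary` rasters; plus `truth`, `data`
#'   (the shared [prepare_data()] result), `resource_points`,
#'   `biotic_layer` and the echoed `config`.
#' @export
run_comparison <- function(config = default_config(), make_maps = TRUE) {
  e <- config$extent
  spec <- grid_spec(e[["lon_min"]], e[["lon_max"]], e[["lat_min"]],
                    e[["lat_max"]], config$cell_size)
  truth <- synthetic_truth(
    spec = spec, n_layers = config$n_layers, smoothness = config$smoothness,
    n_signal = config$n_signal, delta = config$delta,
    lat_cut = config$lat_cut, threshold = config$threshold,
    target_cells = config$target_cells, seed = config$seed)
  occ <- sample_occurrences(truth$suitability, n = config$n_occurrences,
                            n_sites = config$n_sites,
                            seed = config$seed + 101)
  resource_pts <- sample_resource_points(truth$resource_mask,
                                         n = config$n_resource,
                                         seed = config$seed + 102)
  data <- prepare_data(occ, truth$stack, min_km = config$min_km,
                       test_fraction = config$test_fraction,
                       n_background = config$n_background,
                       thin_reps = config$thin_reps,
                       seed = config$seed + 103)
  biotic <- rasterize_buffer(resource_pts, radius_km = config$radius_km,
                             spec = spec,
                             nodata = stack_nodata_mask(truth$stack))

  models <- list()
  for (which in c("abiotic", "biotic_only", "abiotic_plus_biotic")) {
    st <- variant_stack(truth$stack, biotic, which)
    Xtr <- extract_at_points(st, data$train)
    Xte <- extract_at_points(st, data$test)
    Xbg <- extract_at_points(st, data$background)
    fit <- maxent_fit(Xtr, Xbg, beta_multiplier = config$beta_multiplier)
    ev <- evaluate_predictions(predict_logistic(fit, Xte),
                               predict_logistic(fit, Xbg),
                               grid = config$threshold_grid)
    contrib <- contribution_table(fit, Xtr, Xbg, n_perm = config$n_perm,
                                  seed = config$seed + 104)
    entry <- list(model = fit, evaluation = ev, contribution = contrib)
    if (make_maps) {
      suit <- predict_logistic(fit, st)
      suit$name <- paste0(which, "_suitability")
      entry$suitability <- suit
      entry$binary <- binarize(suit, ev$max_kappa_threshold)
    }
    models[[which]] <- entry
  }
  structure(list(models = models, truth = truth, data = data,
                 resource_points = resource_pts, biotic_layer = biotic,
                 config = config),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report (delta = %g, seed = %d)\n",
              x$config$delta, x$config$seed))
  print(x$data$counts)
  print(index_table(x))
  invisible(x)
}

#' Overprediction map: cells the climate-only model keeps but the
#' combined model rejects
#'
#' Flags cells predicted present by the abiotic binary map and absent by
#' the abiotic+biotic binary map.
#'
#' @param report A [run_comparison()] report built with
#'   `make_maps = TRUE`.
#' @return Binary [raster_grid()] of flagged cells; attributes
#'   `n_flagged` (count) and `free_region_overlap` (fraction of flagged
#'   cells inside the truth's suitable-but-resource-free region).
#' @export
overprediction_map <- function(report) {
  a <- report$models$abiotic$binary
  c2 <- report$models$abiotic_plus_biotic$binary
  if (is.null(a) || is.null(c2))
    stop("report lacks binary maps; rerun with make_maps = TRUE")
  if (!identical(unclass(a$spec), unclass(c2$spec)))
    stop("binary rasters are on different grids")
  v <- (a$values == 1 & c2$values == 0) + 0
  out <- raster_grid(a$spec, v, name = "overprediction")
  n_flag <- sum(v == 1, na.rm = TRUE)
  fr <- report$truth$free_region
  in_free <- if (n_flag > 0 && !is.null(fr)) {
    flag_idx <- which(v == 1, arr.ind = TRUE)
    key <- function(m) paste(m[, 1], m[, 2])
    mean(key(flag_idx) %in% key(fr))
  } else NA_real_
  attr(out, "n_flagged") <- n_flag
  attr(out, "free_region_overlap") <- in_free
  out
}

#' Six-index comparison table with best-model marking
#'
#' One row per performance index, one column per model, plus a `best`
#' column naming the best model per row: higher is better for AUC of
#' ROC, AUC of Kappa, overall performance and the correlation; lower is
#' better for the commission and omission AUCs.
#'
#' @param report A [run_comparison()] report.
#' @return Data.frame with columns `index`, one per model, and `best`.
#' @export
index_table <- function(report) {
  idx <- c(auc_roc = "AUC of ROC", auc_kappa = "AUC of Kappa",
           auc_overall_performance = "AUC of Overall Performance",
           auc_commission = "AUC of Commission Index",
           auc_omission = "AUC of Omission Index",
           pearson_cor = "Pearson's Correlation Coefficient")
  lower_better <- c(auc_commission = TRUE, auc_omission = TRUE)
  mods <- names(report$models)
  rows <- lapply(names(idx), function(k) {
    vals <- vapply(mods, function(mn)
      report$models[[mn]]$evaluation[[k]], numeric(1))
    best <- if (isTRUE(lower_better[k])) mods[which.min(vals)]
            else mods[which.max(vals)]
    c(list(index = idx[[k]]), as.list(vals), list(best = best))
  })
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Contribution listings above a cutoff
#'
#' @param report A [run_comparison()] report.
#' @param cutoff Keep variables whose percent contribution OR permutation
#'   importance exceeds this value (default 7.5).
#' @return Named list of data.frames, one per model.
#' @export
contribution_tables <- function(report, cutoff = 7.5) {
  lapply(report$models, function(m) {
    ct <- m$contribution
    ct[ct$percent_contribution > cutoff |
         ct$permutation_importance > cutoff, , drop = FALSE]
  })
}

#' Write the comparison outputs to a directory
#'
#' Emits `indices.csv` (six-index table with best marking), per-model
#' `contribution_<model>.csv`, the continuous and binary suitability
#' rasters as ASCII grids (when present), the overprediction raster,
#' and `report.json` with counts, seeds and the config echo.
#'
#' @param report A [run_comparison()] report.
#' @param dir Output directory (created if needed).
#' @param cutoff Passed to [contribution_tables()].
#' @return `dir`, invisibly.
#' @export
emit_tables <- function(report, dir, cutoff = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(index_table(report), file.path(dir, "indices.csv"),
                   row.names = FALSE)
  ct <- contribution_tables(report, cutoff = cutoff)
  for (mn in names(ct))
    utils::write.csv(ct[[mn]],
                     file.path(dir, sprintf("contribution_%s.csv", mn)),
                     row.names = FALSE)
  has_maps <- !is.null(report$models$abiotic$suitability)
  if (has_maps) {
    for (mn in names(report$models)) {
      write_raster(report$models[[mn]]$suitability,
                   file.path(dir, sprintf("%s_suitability.asc", mn)))
      write_raster(report$models[[mn]]$binary,
                   file.path(dir, sprintf("%s_binary.asc", mn)))
    }
    write_raster(overprediction_map(report),
                 file.path(dir, "overprediction.asc"))
  }
  meta <- list(config = unclass(report$config),
               counts = as.list(report$data$counts),
               models = lapply(report$models, function(m)
                 m$evaluation[c("auc_roc", "auc_kappa",
                                "auc_overall_performance",
                                "auc_commission", "auc_omission",
                                "pearson_cor", "max_kappa_threshold")]))
  jsonlite::write_json(meta, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
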