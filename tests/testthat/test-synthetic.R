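# Synthetic landscape generator: determinism, standardization,
# autocorrelation control, resource range, truth surface and sampling.

test_that("climate stack is reproducible, standardized and autocorrelated", {
  s <- tiny_spec()
  st1 <- generate_climate_stack(s, n_layers = 3, smoothness = 2, seed = 9)
  st2 <- generate_climate_stack(s, n_layers = 3, smoothness = 2, seed = 9)
  expect_equal(st1$layers[[2]]$values, st2$layers[[2]]$values)
  for (l in st1$layers) {
    expect_lt(abs(mean(l$values)), 1e-9)
    expect_equal(stats::sd(l$values), 1, tolerance = 1e-9)
  }
  # lag-1 neighbor correlation grows with the smoothing length
  lag1 <- function(v) stats::cor(as.vector(v[, -1]), as.vector(v[, -ncol(v)]))
  sm1 <- generate_climate_stack(s, 1, smoothness = 1, seed = 4)
  sm20 <- generate_climate_stack(s, 1, smoothness = 6, seed = 4)
  expect_gt(lag1(sm20$layers[[1]]$values), lag1(sm1$layers[[1]]$values))
  expect_error(generate_climate_stack(s, 0, 2, 1), "n_layers")
})

test_that("resource range respects the latitudinal cut and free region", {
  s <- tiny_spec()
  st <- generate_climate_stack(s, 3, 2, seed = 21)
  # threshold -> -Inf keeps every cell north of the cut
  m <- generate_resource_range(s, st, lat_cut = 0, threshold = -Inf,
                               target_cells = NULL, seed = 5)
  lats <- matrix(rep(cell_lats(s), s$n_cols), s$n_rows)
  expect_true(all(m$values[lats > 0] == 1))
  expect_true(all(m$values[lats <= 0] == 0))
  # lat_cut at the southern edge: mask limited only by the latent field
  m2 <- generate_resource_range(s, st, lat_cut = s$lat_min,
                                target_cells = 40, seed = 5)
  expect_equal(sum(m2$values == 1), 40)
  # truth construction yields a nonempty overprediction-prone region
  tr <- suppressWarnings(synthetic_truth(spec = s, n_layers = 4,
                                         n_signal = 2, target_cells = 60,
                                         seed = 3))
  expect_gt(nrow(tr$free_region), 0)
})

test_that("true suitability composes climate part and biotic mask", {
  s <- tiny_spec()
  st <- generate_climate_stack(s, 2, 2, seed = 7)
  mask_v <- matrix(0, s$n_rows, s$n_cols); mask_v[1:5, ] <- 1
  mask <- raster_grid(s, mask_v, name = "resource")
  co <- list(intercept = 0.3, linear = c(1, 0), quadratic = c(-0.5, 0))
  s1 <- true_suitability(st, mask, co, delta = 1)
  expect_true(all(s1$values[mask_v == 0] == 0))
  expect_true(all(s1$values >= 0 & s1$values <= 1))
  # delta = 0 ignores the mask entirely
  mask_all <- raster_grid(s, matrix(1, s$n_rows, s$n_cols), name = "r")
  s0a <- true_suitability(st, mask, co, delta = 0)
  s0b <- true_suitability(st, mask_all, co, delta = 0)
  expect_equal(s0a$values, s0b$values)
  # zero coefficients give a flat logistic(intercept) surface
  flat <- true_suitability(st, mask_all,
                           list(intercept = 0.7, linear = c(0, 0),
                                quadratic = c(0, 0)), delta = 0)
  expect_true(all(abs(flat$values - stats::plogis(0.7)) < 1e-12))
})

test_that("occurrence sampling follows the suitability surface", {
  s <- tiny_spec()
  tr <- synthetic_truth(spec = s, n_layers = 3, n_signal = 2,
                        target_cells = 60, delta = 1, seed = 2)
  occ <- sample_occurrences(tr$suitability, n = 200, seed = 31)
  occ_rep <- sample_occurrences(tr$suitability, n = 200, seed = 31)
  expect_equal(occ$longitude, occ_rep$longitude)
  # delta = 1: every record falls in an occupied cell
  rc <- cell_of_point(s, occ$longitude, occ$latitude)
  expect_true(all(tr$resource_mask$values[cbind(rc$row, rc$col)] == 1))
  # sampled cells are suitability-biased upward
  tr0 <- synthetic_truth(spec = s, n_layers = 3, n_signal = 2,
                         target_cells = 60, delta = 0, seed = 2)
  occ0 <- sample_occurrences(tr0$suitability, n = 500, seed = 32)
  rc0 <- cell_of_point(s, occ0$longitude, occ0$latitude)
  at_pts <- tr0$suitability$values[cbind(rc0$row, rc0$col)]
  expect_gt(mean(at_pts), mean(tr0$suitability$values))
  expect_error(sample_occurrences(
    raster_grid(s, matrix(0, s$n_rows, s$n_cols)), 10, 1), "mass")
})

test_that("delta=0 occurrences hit the mask at its suitability share", {
  s <- tiny_spec()
  tr0 <- synthetic_truth(spec = s, n_layers = 3, n_signal = 2,
                         target_cells = 80, delta = 0, seed = 6)
  n <- 500
  occ <- sample_occurrences(tr0$suitability, n = n, seed = 33)
  rc <- cell_of_point(s, occ$longitude, occ$latitude)
  inside <- mean(tr0$resource_mask$values[cbind(rc$row, rc$col)] == 1)
  share <- sum(tr0$suitability$values[tr0$resource_mask$values == 1]) /
    sum(tr0$suitability$values)
  se <- sqrt(share * (1 - share) / n)
  expect_lt(abs(inside - share), 3 * se)
})

test_that("site-clustered sampling keeps records within their cells", {
  s <- tiny_spec()
  tr <- synthetic_truth(spec = s, n_layers = 3, n_signal = 2,
                        target_cells = 60, delta = 1, seed = 2)
  occ <- sample_occurrences(tr$suitability, n = 150, seed = 8,
                            n_sites = 40)
  rc <- cell_of_point(s, occ$longitude, occ$latitude)
  expect_true(all(tr$resource_mask$values[cbind(rc$row, rc$col)] == 1))
  # clustering compresses the set of distinct occupied cells
  key <- paste(rc$row, rc$col)
  expect_lte(length(unique(key)), 40)
})

test_that("the synthetic reference archive mirrors the published counts", {
  arch <- synthetic_reference_occurrences()
  expect_equal(nrow(arch$focal), 319)
  expect_equal(nrow(arch$resource), 117)
  expect_true(all(filter_effort(arch$focal)$accept))
  # shipped CSVs are the same archive
  f <- system.file("extdata", "woodpecker_records_synthetic.csv",
                   package = "bioticrange")
  expect_equal(nrow(read_points(f)), 319)
})
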