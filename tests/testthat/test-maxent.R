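# Maximum-entropy core: feature expansion, L1 fit, prediction,
# contribution and importance diagnostics.

test_that("feature expansion respects class rules and [0,1] scaling", {
  set.seed(61)
  bg <- cbind(x = rnorm(100), b = rbinom(100, 1, 0.4), k = rep(2, 100))
  pr <- cbind(x = rnorm(90, 1), b = rbinom(90, 1, 0.8), k = rep(2, 90))
  expect_warning(
    fs <- expand_features(pr, bg,
                          classes = c("linear", "quadratic", "hinge")),
    "constant")
  cls <- vapply(fs$features, `[[`, character(1), "class")
  vars <- vapply(fs$features, function(f) f$vars[1], character(1))
  # binary variable becomes exactly one untransformed indicator
  expect_equal(sum(vars == "b"), 1)
  expect_equal(cls[vars == "b"], "categorical")
  # constant variable emits nothing
  expect_false("k" %in% vars)
  # every feature maps the background into [0, 1]
  Fb <- feature_matrix(fs, bg)
  expect_true(all(Fb >= 0 & Fb <= 1))
  # hinge endpoints: 0 at the knot, 1 at the background maximum
  hj <- which(cls == "hinge")[1]
  f <- fs$features[[hj]]
  expect_equal(unname(feature_matrix(fs, cbind(x = f$knot, b = 0,
                                               k = 2))[, hj]), 0)
  expect_equal(unname(feature_matrix(fs, cbind(x = f$hi, b = 0,
                                               k = 2))[, hj]), 1)
  # presence-count schedule
  expect_equal(default_classes(5), "linear")
  expect_true("hinge" %in% default_classes(20))
  expect_true("product" %in% default_classes(85))
})

test_that("unpenalized single-binary-feature fit matches the closed form", {
  bg <- matrix(c(rep(1, 50), rep(0, 50)), ncol = 1,
               dimnames = list(NULL, "b"))
  pr <- matrix(c(rep(1, 80), rep(0, 20)), ncol = 1,
               dimnames = list(NULL, "b"))
  fit <- maxent_fit(pr, bg, beta_multiplier = 0, tol = 1e-9,
                    add_samples_to_background = FALSE)
  expect_equal(fit$lambda, log(4), tolerance = 1e-4)
  raw <- predict_raw(fit, bg)
  expect_equal(sum(raw), 1, tolerance = 1e-9)
  # per-cell mass: 0.016 on f=1 cells, 0.004 on f=0 cells
  expect_equal(unique(round(raw, 6)), c(0.016, 0.004))
})

test_that("beta = 0 fits match presence moments and the optim oracle", {
  for (s in 1:5) {
    set.seed(s)
    bg <- matrix(rnorm(120), 60, 2, dimnames = list(NULL, c("a", "b")))
    # presences resampled from the background with exponential tilting,
    # so the unpenalized maxent solution is finite and interior
    rows <- sample.int(60, 40, replace = TRUE,
                       prob = exp(0.8 * bg[, 1] - 0.4 * bg[, 2]))
    pr <- bg[rows, , drop = FALSE]
    fit <- maxent_fit(pr, bg, beta_multiplier = 0, tol = 1e-9,
                      classes = c("linear", "quadratic"),
                      add_samples_to_background = FALSE)
    Fb <- feature_matrix(fit$features, bg)
    Fp <- feature_matrix(fit$features, pr)
    w <- predict_raw(fit, bg)
    expect_lt(max(abs(colSums(Fb * w) - colMeans(Fp))), 1e-4)
    # independent route: generic optimizer on the same objective
    negll <- function(l) {
      eta <- Fb %*% l
      -mean(Fp %*% l) + log(sum(exp(eta)))
    }
    o <- stats::optim(rep(0, ncol(Fb)), negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
    expect_equal(-mean(Fp %*% fit$lambda) +
                   log(sum(exp(Fb %*% fit$lambda))),
                 o$value, tolerance = 1e-5)
  }
})

test_that("raw scores normalize and the logistic output is calibrated", {
  d <- toy_pb(seed = 62)
  fit <- maxent_fit(d$presence, d$background,
                    classes = c("linear", "quadratic", "hinge"))
  # raw sums to 1 over the normalization sample (background + samples)
  zset <- rbind(d$background, d$presence)
  expect_equal(sum(predict_raw(fit, zset)), 1, tolerance = 1e-9)
  # an effectively unpenalized-to-zero model scores 0.5 everywhere
  fit0 <- maxent_fit(d$presence, d$background, beta_multiplier = 1e9)
  expect_true(all(abs(predict_logistic(fit0, d$background) - 0.5) < 1e-12))
  # logistic is a monotone transform of raw: identical ROC AUC
  labels <- c(rep(0, nrow(d$background)), rep(1, nrow(d$presence)))
  expect_equal(roc_auc(predict_raw(fit, zset), labels),
               roc_auc(predict_logistic(fit, zset), labels))
})

test_that("total L1 norm shrinks as the penalty multiplier grows", {
  d <- toy_pb(seed = 63)
  norms <- vapply(c(0.5, 1, 2, 4), function(bm)
    sum(abs(maxent_fit(d$presence, d$background, beta_multiplier = bm,
                       classes = c("linear", "quadratic", "hinge"))$lambda)),
    numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("models serialize to JSON and predict identically after reload", {
  d <- toy_pb(seed = 64)
  fit <- maxent_fit(d$presence, d$background,
                    classes = c("linear", "hinge"))
  path <- tempfile(fileext = ".json")
  write_model(fit, path)
  fit2 <- read_model(path)
  newx <- d$background[1:20, ]
  expect_equal(predict_logistic(fit2, newx), predict_logistic(fit, newx),
               tolerance = 1e-12)
  expect_equal(percent_contribution(fit2)$percent_contribution,
               percent_contribution(fit)$percent_contribution,
               tolerance = 1e-12)
})

test_that("percent contribution credits gain to the informative variable", {
  d <- toy_pb(seed = 65)
  # single variable: trivially 100
  fit1 <- maxent_fit(d$presence[, "x", drop = FALSE],
                     d$background[, "x", drop = FALSE],
                     classes = c("linear", "quadratic"))
  pc1 <- percent_contribution(fit1)
  expect_equal(pc1$percent_contribution, 100)
  # signal vs noise
  fit <- maxent_fit(d$presence, d$background,
                    classes = c("linear", "quadratic", "hinge"))
  pc <- percent_contribution(fit)
  expect_equal(sum(pc$percent_contribution), 100, tolerance = 1e-6)
  expect_lt(pc$percent_contribution[pc$variable == "noise"], 5)
  expect_equal(pc$variable[1], "x")
})

test_that("permutation importance tracks unique predictive information", {
  d <- toy_pb(seed = 66)
  fit <- maxent_fit(d$presence, d$background,
                    classes = c("linear", "quadratic"))
  pi <- permutation_importance(fit, d$presence, d$background,
                               n_perm = 3, seed = 5)
  expect_equal(sum(pi$permutation_importance), 100, tolerance = 1e-6)
  expect_equal(pi$variable[1], "x")
  # a variable whose features all carry zero weight has zero importance
  lam_by_var <- vapply(seq_along(fit$features$features), function(j)
    fit$features$features[[j]]$vars[1], character(1))
  if (all(fit$lambda[lam_by_var == "noise"] == 0))
    expect_equal(pi$permutation_importance[pi$variable == "noise"], 0)
  expect_error(permutation_importance(fit, d$presence[0, , drop = FALSE],
                                      d$background[0, , drop = FALSE]),
               "2 rows")
})

test_that("response curves reflect fitted structure", {
  d <- toy_pb(seed = 67)
  # flat at 0.5 for the uniform (all-zero) model
  fit0 <- maxent_fit(d$presence, d$background, beta_multiplier = 1e9)
  rc0 <- response_curve(fit0, "x", d$background)
  expect_true(all(abs(rc0$logistic - 0.5) < 1e-12))
  # single positive linear feature: monotone increasing curve
  fit1 <- maxent_fit(d$presence[, "x", drop = FALSE],
                     d$background[, "x", drop = FALSE],
                     classes = "linear")
  expect_gt(fit1$lambda[1], 0)
  rc1 <- response_curve(fit1, "x", d$background[, "x", drop = FALSE])
  expect_true(all(diff(rc1$logistic) >= 0))
  # binary variable: two-point curve
  set.seed(68)
  bgb <- cbind(r = rbinom(80, 1, 0.3))
  prb <- cbind(r = rbinom(50, 1, 0.9))
  fitb <- maxent_fit(prb, bgb)
  rcb <- response_curve(fitb, "r", bgb)
  expect_equal(nrow(rcb), 2)
  expect_gt(rcb$logistic[2], rcb$logistic[1])
})
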