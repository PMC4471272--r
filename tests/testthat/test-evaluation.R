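# Six-index evaluation suite: confusion matrices, kappa and error rates,
# threshold sweeps, ROC AUC, point-biserial correlation, binarization.

toy_scores <- c(0.9, 0.8, 0.6, 0.7, 0.4, 0.3, 0.2, 0.1)
toy_labels <- c(1, 1, 1, 0, 0, 0, 0, 0)

test_that("confusion matrices count the >= t rule correctly", {
  cm <- confusion_at(toy_scores, toy_labels, 0.5)
  expect_equal(unclass(cm), c(tp = 3L, fp = 1L, fn = 0L, tn = 4L))
  cm0 <- confusion_at(toy_scores, toy_labels, 0)
  expect_equal(cm0[["fn"]] + cm0[["tn"]], 0L)
  cmx <- confusion_at(toy_scores, toy_labels, 0.91)
  expect_equal(cmx[["tp"]] + cmx[["fp"]], 0L)
  # ties predict presence
  expect_equal(confusion_at(c(0.5, 0.5), c(1, 0), 0.5)[["tp"]], 1L)
  expect_error(confusion_at(c(1, 2), c(1, 1), 0.5), "absence")
})

test_that("metric suite reproduces hand-computed values and conventions", {
  m <- metric_suite(c(tp = 3, fp = 1, fn = 2, tn = 4))
  expect_equal(m[["overall_performance"]], 0.7)
  expect_equal(m[["commission"]], 0.2)
  expect_equal(m[["omission"]], 0.4)
  expect_equal(m[["kappa"]], 0.4)   # p_o = 0.7, p_e = 0.5
  perfect <- metric_suite(c(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_equal(unname(perfect),
               c(1, 1, 0, 0)[match(names(perfect),
                                   c("kappa", "overall_performance",
                                     "commission", "omission"))])
  # degenerate margins follow the documented conventions
  expect_equal(metric_suite(c(tp = 3, fp = 0, fn = 1, tn = 0))[["commission"]], 0)
  expect_equal(metric_suite(c(tp = 0, fp = 2, fn = 0, tn = 2))[["omission"]], 0)
  expect_equal(metric_suite(c(tp = 4, fp = 0, fn = 0, tn = 0))[["kappa"]], 0)
  # ranges hold on random confusion matrices
  set.seed(71)
  for (i in 1:200) {
    cm <- c(tp = rpois(1, 3), fp = rpois(1, 3), fn = rpois(1, 3),
            tn = rpois(1, 3))
    if (sum(cm) == 0) next
    m <- metric_suite(cm)
    expect_true(m[["kappa"]] >= -1 && m[["kappa"]] <= 1)
    expect_true(all(m[c("overall_performance", "commission",
                        "omission")] >= 0 &
                    m[c("overall_performance", "commission",
                        "omission")] <= 1))
  }
})

test_that("label-independent predictions give kappa near zero", {
  set.seed(72)
  ks <- replicate(1000, {
    labels <- c(rep(1, 10), rep(0, 20))
    scores <- sample(seq(0, 1, length.out = 30))
    metric_suite(confusion_at(scores, labels, 0.5))[["kappa"]]
  })
  expect_lt(abs(mean(ks)), 0.02)
})

test_that("threshold curves integrate correctly and are monotone", {
  grid <- default_threshold_grid()
  cc <- threshold_curve(toy_scores, toy_labels, "commission", grid)
  oc <- threshold_curve(toy_scores, toy_labels, "omission", grid)
  expect_true(all(diff(cc$value) <= 0))
  expect_true(all(diff(oc$value) >= 0))
  # constant metric c integrates to c
  const <- structure(data.frame(threshold = grid,
                                value = rep(0.37, length(grid))))
  expect_equal(auc_of_curve(const), 0.37)
  # two-segment piecewise-linear toy curve against the hand trapezoid
  toy <- data.frame(threshold = c(0, 0.5, 1), value = c(0, 1, 0.5))
  expect_equal(auc_of_curve(toy), (0.5 * (0 + 1) / 2 +
                                     0.5 * (1 + 0.5) / 2) / 1)
  # overall_performance identity: 1 - (fp + fn)/n at every threshold
  op <- threshold_curve(toy_scores, toy_labels, "overall_performance", grid)
  for (i in seq(1, length(grid), by = 10)) {
    cm <- confusion_at(toy_scores, toy_labels, grid[i])
    expect_equal(op$value[i], 1 - (cm[["fp"]] + cm[["fn"]]) / sum(cm))
  }
  expect_error(threshold_curve(toy_scores, toy_labels, "kappa",
                               c(0.5, 0.2)), "increasing")
})

test_that("rank-based ROC AUC equals exhaustive pair counting", {
  expect_equal(roc_auc(toy_scores, toy_labels), 14 / 15)
  expect_equal(oracle_auc(toy_scores, toy_labels), 14 / 15)
  expect_equal(roc_auc(c(5, 4, 3, 2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.3, 10), rep(c(1, 0), 5)), 0.5)
  set.seed(73)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    scores <- round(runif(n), 2)      # heavy ties
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  }
  expect_error(roc_auc(c(1, 2), c(1, 1)), "nonempty")
})

test_that("point-biserial correlation matches closed forms", {
  expect_equal(pearson_cor(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  labels <- c(1, 1, 0, 0); preds <- c(0.8, 0.6, 0.4, 0.2)
  expect_equal(pearson_cor(preds, labels), stats::cor(preds, labels))
  expect_equal(pearson_cor(-preds, labels), -pearson_cor(preds, labels))
  expect_error(pearson_cor(rep(0.5, 4), labels), "variance")
})

test_that("max-kappa threshold takes the smallest maximizing grid point", {
  grid <- default_threshold_grid()
  # perfectly separated: kappa = 1 on a plateau; smallest grid point wins
  sep_scores <- c(0.9, 0.8, 0.2, 0.1)
  sep_labels <- c(1, 1, 0, 0)
  t_star <- max_kappa_threshold(sep_scores, sep_labels, grid)
  kap <- threshold_curve(sep_scores, sep_labels, "kappa", grid)
  expect_equal(t_star, min(kap$threshold[kap$value == max(kap$value)]))
  expect_equal(t_star, 0.21)
  # toy set against an exhaustive sweep
  t8 <- max_kappa_threshold(toy_scores, toy_labels, grid)
  kaps <- vapply(grid, function(t)
    metric_suite(confusion_at(toy_scores, toy_labels, t))[["kappa"]],
    numeric(1))
  expect_equal(t8, grid[which.max(kaps)])
})

test_that("binarization respects the threshold and nodata", {
  s <- tiny_spec()
  set.seed(74)
  v <- matrix(runif(s$n_rows * s$n_cols), s$n_rows)
  v[1, 1] <- NA
  r <- raster_grid(s, v, name = "suit")
  b <- binarize(r, 0.5)
  expect_true(all(b$values[!is.na(b$values)] %in% c(0, 1)))
  expect_true(is.na(b$values[1, 1]))
  expect_equal(b$values[2, 2], as.numeric(v[2, 2] >= 0.5))
  ball <- binarize(r, 0)
  expect_true(all(ball$values[!is.na(ball$values)] == 1))
})

test_that("evaluation reports are complete and deterministic", {
  set.seed(75)
  pp <- runif(30, 0.3, 1); pa <- runif(100, 0, 0.7)
  r1 <- evaluate_predictions(pp, pa)
  r2 <- evaluate_predictions(pp, pa)
  for (k in c("auc_roc", "auc_kappa", "auc_overall_performance",
              "auc_commission", "auc_omission", "pearson_cor",
              "max_kappa_threshold"))
    expect_identical(r1[[k]], r2[[k]])
  expect_true(r1$auc_roc >= 0 && r1$auc_roc <= 1)
  expect_equal(r1$auc_roc,
               oracle_auc(c(pp, pa), c(rep(1, 30), rep(0, 100))))
  expect_length(r1$curves, 4)
})
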