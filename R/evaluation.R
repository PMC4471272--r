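# Threshold-dependent and threshold-independent model evaluation: the
# confusion matrix, Cohen's kappa, overall performance (correct
# classification rate), commission and omission rates, their
# threshold-sweep curves and areas under those curves, rank-based ROC
# AUC, the point-biserial presence/absence correlation, and max-kappa
# binarization.

#' Confusion matrix at a threshold
#'
#' A point is predicted positive iff its score is `>= t` (ties predict
#' presence).
#'
#' @param predictions Numeric scores.
#' @param labels 0/1 (or logical) observed presence labels.
#' @param t Threshold.
#' @return Named integer vector `c(tp, fp, fn, tn)` of class
#'   `confusion_matrix`.
#' @export
confusion_at <- function(predictions, labels, t) {
  labels <- as.integer(as.logical(labels))
  if (length(predictions) != length(labels))
    stop("predictions and labels must have equal length")
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("need at least one presence and one absence")
  pos <- predictions >= t
  structure(c(tp = sum(pos & labels == 1L),
              fp = sum(pos & labels == 0L),
              fn = sum(!pos & labels == 1L),
              tn = sum(!pos & labels == 0L)),
            class = "confusion_matrix")
}

#' The four threshold-dependent indices of a confusion matrix
#'
#' * `overall_performance` (correct classification rate) = (tp+tn)/n
#' * `commission` (false positive rate) = fp/(fp+tn), 0 if fp+tn = 0
#' * `omission` (false negative rate) = fn/(fn+tp), 0 if fn+tp = 0
#' * `kappa` = (p_o - p_e)/(1 - p_e) with p_o the observed agreement and
#'   p_e the chance agreement from the margins; 0 if p_e = 1
#'
#' @param cm A [confusion_at()] result (or any named vector with
#'   tp/fp/fn/tn).
#' @return Named numeric vector with the four indices.
#' @export
metric_suite <- function(cm) {
  tp <- as.numeric(cm[["tp"]]); fp <- as.numeric(cm[["fp"]])
  fn <- as.numeric(cm[["fn"]]); tn <- as.numeric(cm[["tn"]])
  n <- tp + fp + fn + tn
  if (n <= 0) stop("empty confusion matrix")
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  c(kappa = if (pe >= 1) 0 else (po - pe) / (1 - pe),
    overall_performance = po,
    commission = if (fp + tn == 0) 0 else fp / (fp + tn),
    omission = if (fn + tp == 0) 0 else fn / (fn + tp))
}

#' Default threshold grid (101 points, 0 to 1 by 0.01)
#' @export
default_threshold_grid <- function() seq(0, 1, by = 0.01)

#' Metric value along a threshold sweep
#'
#' @inheritParams confusion_at
#' @param metric One of `kappa`, `overall_performance`, `commission`,
#'   `omission`.
#' @param grid Increasing threshold grid in `[0, 1]`.
#' @return Object of class `threshold_curve`: data.frame with
#'   `threshold` and `value`; attribute `metric`.
#' @export
threshold_curve <- function(predictions, labels, metric,
                            grid = default_threshold_grid()) {
  metric <- match.arg(metric, c("kappa", "overall_performance",
                                "commission", "omission"))
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing")
  vals <- vapply(grid, function(t)
    metric_suite(confusion_at(predictions, labels, t))[[metric]],
    numeric(1))
  structure(data.frame(threshold = grid, value = vals),
            metric = metric, class = c("threshold_curve", "data.frame"))
}

#' Normalized area under a threshold curve
#'
#' Trapezoidal rule over the threshold axis divided by the axis span, so
#' a constant curve at value c has area c.
#'
#' @param curve A [threshold_curve()] (or data.frame with `threshold`,
#'   `value`).
#' @return Scalar area.
#' @export
auc_of_curve <- function(curve) {
  t <- curve$threshold; v <- curve$value
  if (length(t) < 2L) return(v[1L])
  sum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2) /
    (t[length(t)] - t[1L])
}

#' Threshold-independent ROC AUC
#'
#' Computed as the Mann-Whitney statistic via mid-ranks:
#' `P(score_presence > score_absence) + 0.5 * P(tie)` over all
#' presence-absence pairs.
#'
#' @inheritParams confusion_at
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(predictions, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be nonempty")
  if (anyNA(predictions)) stop("predictions contain NA")
  r <- rank(predictions, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Point-biserial correlation between labels and predictions
#'
#' Pearson product-moment correlation between the 0/1 presence labels
#' and the continuous model predictions.
#'
#' @inheritParams confusion_at
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_cor <- function(predictions, labels) {
  labels <- as.integer(as.logical(labels))
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("both classes must be nonempty")
  if (stats::sd(predictions) == 0)
    stop("predictions have zero variance; correlation undefined")
  stats::cor(predictions, labels)
}

#' Threshold maximizing kappa
#'
#' @inheritParams threshold_curve
#' @return The smallest grid threshold attaining the maximum kappa.
#' @export
max_kappa_threshold <- function(predictions, labels,
                                grid = default_threshold_grid()) {
  curve <- threshold_curve(predictions, labels, "kappa", grid)
  curve$threshold[which.max(curve$value)]
}

#' Binarize a suitability raster at a threshold
#'
#' @param raster A [raster_grid()] of continuous scores.
#' @param t Threshold; cells with score `>= t` become 1.
#' @return Binary [raster_grid()] (nodata preserved).
#' @export
binarize <- function(raster, t) {
  v <- (raster$values >= t) + 0
  raster_grid(raster$spec, v, name = paste0(raster$name, "_bin"))
}

#' Full six-index evaluation report
#'
#' Computes the four threshold-sweep curves (kappa, overall performance,
#' commission, omission) with their normalized areas, the rank-based ROC
#' AUC, the point-biserial correlation, and the max-kappa threshold.
#'
#' @param pred_presence Scores at test presences.
#' @param pred_absence Scores at pseudo-absences.
#' @param grid Threshold grid.
#' @return Object of class `evaluation_report`: list with `auc_roc`,
#'   `auc_kappa`, `auc_overall_performance`, `auc_commission`,
#'   `auc_omission`, `pearson_cor`, `max_kappa_threshold`, `curves`
#'   (named list of [threshold_curve()]s) and the input sizes.
#' @export
evaluate_predictions <- function(pred_presence, pred_absence,
                                 grid = default_threshold_grid()) {
  if (length(pred_presence) < 1L || length(pred_absence) < 1L)
    stop("need at least one presence and one pseudo-absence score")
  predictions <- c(pred_presence, pred_absence)
  labels <- c(rep(1L, length(pred_presence)),
              rep(0L, length(pred_absence)))
  curves <- lapply(
    stats::setNames(nm = c("kappa", "overall_performance", "commission",
                           "omission")),
    function(mt) threshold_curve(predictions, labels, mt, grid))
  structure(list(
    auc_roc = roc_auc(predictions, labels),
    auc_kappa = auc_of_curve(curves$kappa),
    auc_overall_performance = auc_of_curve(curves$overall_performance),
    auc_commission = auc_of_curve(curves$commission),
    auc_omission = auc_of_curve(curves$omission),
    # a constant predictor (e.g. a fully shrunk model) has no defined
    # point-biserial correlation; report NA rather than fail
    pearson_cor = if (stats::sd(predictions) == 0) NA_real_
                  else pearson_cor(predictions, labels),
    max_kappa_threshold =
      curves$kappa$threshold[which.max(curves$kappa$value)],
    curves = curves,
    n_presence = length(pred_presence),
    n_absence = length(pred_absence)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    paste0("evaluation_report (%d presences vs %d pseudo-absences)\n",
           "  AUC of ROC                 %.3f\n",
           "  AUC of Kappa               %.3f\n",
           "  AUC of Overall Performance %.3f\n",
           "  AUC of Commission Index    %.3f\n",
           "  AUC of Omission Index      %.3f\n",
           "  Pearson's correlation      %.3f\n",
           "  max-kappa threshold        %.2f\n"),
    x$n_presence, x$n_absence, x$auc_roc, x$auc_kappa,
    x$auc_overall_performance, x$auc_commission, x$auc_omission,
    x$pearson_cor, x$max_kappa_threshold))
  invisible(x)
}
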