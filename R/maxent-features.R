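# Feature expansion for the presence-background maximum-entropy model.
#
# Raw predictors are transformed into features mapping the background
# into [0, 1]: min-max-scaled linear and quadratic terms, scaled pairwise
# products, forward and reverse hinges at background quantiles, and
# untransformed indicators for binary (categorical) variables.  All
# scaling constants come from the background sample only; projection
# values outside the background range are clamped.

# Which feature classes Maxent-style defaults enable for m presences.
default_classes <- function(m) {
  if (m < 10) c("linear")
  else if (m < 15) c("linear", "quadratic")
  else if (m < 80) c("linear", "quadratic", "hinge")
  else c("linear", "quadratic", "product", "hinge")
}

#' Expand raw predictors into a bounded feature set
#'
#' Builds the feature definitions (with background-derived scaling
#' constants) and the presence/background feature matrices.  Feature
#' classes default to the presence-count schedule used by Maxent
#' (`linear` below 10 presences, adding `quadratic`, then `hinge` at 15,
#' then `product` at 80; threshold features are off by default).  Binary
#' 0/1 variables become a single untransformed indicator feature.
#' Variables constant on the background yield no features (with a
#' warning).
#'
#' @param presence Matrix of raw predictor values at presence points
#'   (named columns).
#' @param background Matrix of raw predictor values at background points
#'   (same columns).
#' @param classes Character vector of feature classes to enable, or
#'   `NULL` for the presence-count default.
#' @param n_knots Hinge knots per variable and direction (default 20,
#'   placed at interior background quantiles).
#' @return Object of class `feature_set`: a list with `features` (one
#'   descriptor per feature), `var_names`, `categorical`, and the enabled
#'   `classes`.
#' @export
expand_features <- function(presence, background, classes = NULL,
                            n_knots = 20) {
  presence <- as.matrix(presence)
  background <- as.matrix(background)
  if (is.null(colnames(background)))
    colnames(background) <- colnames(presence) <-
      paste0("v", seq_len(ncol(background)))
  if (!identical(colnames(presence), colnames(background)))
    stop("presence and background must share column names")
  if (nrow(background) < 1L) stop("background must be nonempty")
  if (any(!is.finite(presence)) || any(!is.finite(background)))
    stop("non-finite predictor values")
  vars <- colnames(background)
  if (is.null(classes)) classes <- default_classes(nrow(presence))

  categorical <- vapply(vars, function(v)
    all(background[, v] %in% c(0, 1)) && all(presence[, v] %in% c(0, 1)),
    logical(1))
  feats <- list()
  add <- function(f) feats[[length(feats) + 1L]] <<- f

  for (v in vars) {
    x <- background[, v]
    lo <- min(x); hi <- max(x)
    if (categorical[[v]]) {
      if (hi > lo)          # constant indicator carries no information
        add(list(class = "categorical", vars = v,
                 name = paste0("cat(", v, ")")))
      next
    }
    if (hi == lo) {
      warning(sprintf("variable '%s' is constant on the background; ",
                      v), "no features emitted", call. = FALSE)
      next
    }
    if ("linear" %in% classes)
      add(list(class = "linear", vars = v, lo = lo, hi = hi,
               name = v))
    if ("quadratic" %in% classes) {
      q <- x^2
      add(list(class = "quadratic", vars = v, lo = min(q), hi = max(q),
               name = paste0(v, "^2")))
    }
    if ("hinge" %in% classes) {
      probs <- seq(0, 1, length.out = n_knots + 2L)[-c(1L, n_knots + 2L)]
      knots <- unique(stats::quantile(x, probs, names = FALSE, type = 7))
      for (k in knots) {
        if (k < hi)
          add(list(class = "hinge", vars = v, knot = k, hi = hi,
                   name = sprintf("hinge(%s,%.6g)", v, k)))
        if (k > lo)
          add(list(class = "rev_hinge", vars = v, knot = k, lo = lo,
                   name = sprintf("revhinge(%s,%.6g)", v, k)))
      }
    }
  }
  if ("product" %in% classes && length(vars) > 1L) {
    cont <- vars[!categorical]
    cont <- cont[vapply(cont, function(v)
      max(background[, v]) > min(background[, v]), logical(1))]
    if (length(cont) > 1L) {
      for (i in seq_len(length(cont) - 1L)) for (j in (i + 1L):length(cont)) {
        p <- background[, cont[i]] * background[, cont[j]]
        if (max(p) > min(p))
          add(list(class = "product", vars = c(cont[i], cont[j]),
                   lo = min(p), hi = max(p),
                   name = paste0(cont[i], "*", cont[j])))
      }
    }
  }
  structure(list(features = feats, var_names = vars,
                 categorical = categorical, classes = classes),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cls <- vapply(x$features, `[[`, character(1), "class")
  cat(sprintf("feature_set: %d features from %d variables\n",
              length(x$features), length(x$var_names)))
  print(table(cls))
  invisible(x)
}

clamp01 <- function(z) pmin(1, pmax(0, z))

#' Evaluate a feature set on raw predictor values
#'
#' @param fs A [expand_features()] feature set.
#' @param X Matrix of raw predictor values with the training columns.
#' @return Numeric matrix, one column per feature, values in `[0, 1]`.
#' @export
feature_matrix <- function(fs, X) {
  X <- as.matrix(X)
  if (!all(fs$var_names %in% colnames(X)))
    stop("missing variable(s): ",
         paste(setdiff(fs$var_names, colnames(X)), collapse = ", "))
  n <- nrow(X)
  out <- matrix(NA_real_, n, length(fs$features))
  for (j in seq_along(fs$features)) {
    f <- fs$features[[j]]
    out[, j] <- switch(f$class,
      categorical = X[, f$vars],
      linear = clamp01((X[, f$vars] - f$lo) / (f$hi - f$lo)),
      quadratic = clamp01((X[, f$vars]^2 - f$lo) / (f$hi - f$lo)),
      product = clamp01((X[, f$vars[1]] * X[, f$vars[2]] - f$lo) /
                          (f$hi - f$lo)),
      hinge = clamp01((X[, f$vars] - f$knot) / (f$hi - f$knot)),
      rev_hinge = clamp01((f$knot - X[, f$vars]) / (f$knot - f$lo)),
      stop("unknown feature class ", f$class))
  }
  colnames(out) <- vapply(fs$features, `[[`, character(1), "name")
  out
}
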