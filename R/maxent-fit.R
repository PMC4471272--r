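# L1-penalized maximum-entropy fitting by cyclic coordinate descent.
#
# The model is the Gibbs distribution over the background sample,
#   P(x) = exp(sum_j lambda_j f_j(x)) / Z,   Z = sum_b exp(eta_b),
# fitted by minimizing the penalized negative mean presence log-likelihood
#   J(lambda) = -mean_i eta(x_i) + log Z + sum_j beta_j |lambda_j|.
# Each coordinate step is a Newton update on the local quadratic model
# with soft-thresholding, accepted only if the exact objective decreases
# (with step halving); the per-step objective decrease ("gain") is logged
# in the training trace, which is what the percent-contribution heuristic
# consumes.

# Per-feature-class multipliers of the default L1 penalty schedule:
# beta_j = base(class) * sd_bg(f_j) / sqrt(m) * beta_multiplier.
BETA_CLASS_BASE <- c(linear = 1.0, quadratic = 1.0, product = 1.0,
                     hinge = 0.5, rev_hinge = 0.5, categorical = 0.25)

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fit a presence-background maximum-entropy model
#'
#' @param presence Matrix of raw predictor values at presence points
#'   (named columns), or values returned by [extract_at_points()].
#' @param background Matrix of raw predictor values at background points.
#' @param beta_multiplier Global multiplier on the per-feature L1
#'   penalties (default 1; 0 gives the unpenalized fit whose feature
#'   expectations match the presence means).
#' @param tol Convergence tolerance on the best single-coordinate
#'   objective gain within a sweep (default 1e-6).
#' @param max_iter Maximum number of full coordinate sweeps (default
#'   2000).
#' @param classes,n_knots Passed to [expand_features()] (`NULL` classes =
#'   presence-count default).
#' @param add_samples_to_background If `TRUE` (default, matching Maxent's
#'   `addsamplestobackground`), the presence samples join the background
#'   for the normalizer Z, which keeps the likelihood bounded when the
#'   feature space would otherwise separate presences from a small
#'   background sample; raw scores then sum to 1 over the combined set.
#' @return Object of class `maxent_model`: feature set, coefficients
#'   `lambda`, penalties `beta`, `log_z` (log normalizer over the
#'   background), `entropy` of the fitted background distribution,
#'   training `trace` (data.frame of sweep, feature, variables, gain),
#'   presence feature means, and convergence info.
#' @export
maxent_fit <- function(presence, background, beta_multiplier = 1,
                       tol = 1e-6, max_iter = 2000, classes = NULL,
                       n_knots = 20, add_samples_to_background = TRUE) {
  presence <- as.matrix(presence)
  background <- as.matrix(background)
  m <- nrow(presence)
  if (m < 1L) stop("need at least one presence")
  if (nrow(unique(background)) < 2L)
    stop("background must contain at least 2 distinct rows")
  fs <- expand_features(presence, background, classes = classes,
                        n_knots = n_knots)
  if (length(fs$features) == 0L)
    warning("no usable features (all variables constant on the ",
            "background); returning the uniform model", call. = FALSE)
  Fp <- feature_matrix(fs, presence)
  Fb <- feature_matrix(fs, background)
  if (any(!is.finite(Fp)) || any(!is.finite(Fb)))
    stop("non-finite feature values")
  # Normalization sample for Z: by default the presence samples join the
  # background (as in Maxent's addsamplestobackground default), which
  # keeps the likelihood bounded when features would otherwise separate
  # the presences from a small background sample.
  if (add_samples_to_background) Fb <- rbind(Fb, Fp)
  J <- ncol(Fb); B <- nrow(Fb)
  fbar <- colMeans(Fp)
  sd_b <- apply(Fb, 2L, stats::sd)
  base <- BETA_CLASS_BASE[vapply(fs$features, `[[`, character(1), "class")]
  beta <- as.numeric(base) * sd_b / sqrt(m) * beta_multiplier

  lambda <- numeric(J)
  eta_b <- numeric(B)
  eta_p_mean <- 0                       # mean over presences of eta
  lz <- log(B)                          # log Z at lambda = 0
  penalty <- 0
  obj <- -eta_p_mean + lz + penalty
  # preallocated, doubling trace buffers (one entry per accepted update)
  cap <- 1024L; n_tr <- 0L
  trace_sweep <- integer(cap); trace_feat <- integer(cap)
  trace_gain <- numeric(cap)
  push_trace <- function(s, j, g) {
    if (n_tr == cap) {
      cap <<- cap * 2L
      length(trace_sweep) <<- cap
      length(trace_feat) <<- cap
      length(trace_gain) <<- cap
    }
    n_tr <<- n_tr + 1L
    trace_sweep[n_tr] <<- s; trace_feat[n_tr] <<- j
    trace_gain[n_tr] <<- g
  }

  w <- rep(1 / B, B)
  sweep <- 0L

  # One coordinate update (Newton + soft-threshold on the local quadratic
  # model, exact-objective step halving); returns the objective gain.
  update_coord <- function(j) {
    fj_b <- Fb[, j]
    Ej <- sum(w * fj_b)
    Vj <- sum(w * fj_b * fj_b) - Ej * Ej
    grad <- Ej - fbar[j]
    if (Vj < 1e-12) {
      if (lambda[j] == 0) return(0)
      Vj <- 1e-12
    }
    target <- soft_threshold(lambda[j] * Vj - grad, beta[j]) / Vj
    delta <- target - lambda[j]
    if (delta == 0) return(0)
    if (abs(delta) > 10) delta <- sign(delta) * 10
    for (h in 1:20) {
      new_lambda_j <- lambda[j] + delta
      new_eta_b <- eta_b + delta * fj_b
      new_lz <- log_sum_exp(new_eta_b)
      new_eta_p_mean <- eta_p_mean + delta * fbar[j]
      new_penalty <- penalty + beta[j] * (abs(new_lambda_j) -
                                            abs(lambda[j]))
      new_obj <- -new_eta_p_mean + new_lz + new_penalty
      if (new_obj < obj - 1e-15) {
        gain <- obj - new_obj
        lambda[j] <<- new_lambda_j
        eta_b <<- new_eta_b
        eta_p_mean <<- new_eta_p_mean
        lz <<- new_lz
        penalty <<- new_penalty
        obj <<- new_obj
        w <<- exp(new_eta_b - new_lz)
        push_trace(sweep, j, gain)
        return(gain)
      }
      delta <- delta / 2
      if (abs(delta) < 1e-14) break
    }
    0
  }

  # Greedy coordinate descent: at every step the feature whose local
  # quadratic model promises the largest penalized gain is updated, so
  # the training trace credits shared signal to the feature that buys
  # the most improvement first -- the behavior the percent-contribution
  # heuristic presumes.  Iterates until the best achieved gain falls
  # below tol or max_iter updates are spent.
  Fb2 <- Fb * Fb
  blocked <- rep(FALSE, J)   # features whose line search failed at this w
  if (J > 0L) repeat {
    sweep <- sweep + 1L
    E_all <- drop(crossprod(Fb, w))
    V_all <- drop(crossprod(Fb2, w)) - E_all * E_all
    grad_all <- E_all - fbar
    Vc <- pmax(V_all, 1e-12)
    z <- lambda * Vc - grad_all
    target_all <- sign(z) * pmax(0, abs(z) - beta) / Vc
    delta_all <- target_all - lambda
    est <- -(grad_all * delta_all + 0.5 * Vc * delta_all^2) -
      beta * (abs(target_all) - abs(lambda))
    est[V_all < 1e-12 & lambda == 0] <- 0
    est[blocked] <- -Inf
    j <- which.max(est)
    if (!is.finite(est[j]) || est[j] <= tol) break
    g <- update_coord(j)
    if (g >= tol) blocked[] <- FALSE else blocked[j] <- TRUE
    if (sweep >= max_iter) break
  }

  entropy <- -sum(w[w > 0] * log(w[w > 0]))
  vars_of <- vapply(fs$features, function(f)
    paste(f$vars, collapse = "*"), character(1))
  trace_sweep <- trace_sweep[seq_len(n_tr)]
  trace_feat <- trace_feat[seq_len(n_tr)]
  trace_gain <- trace_gain[seq_len(n_tr)]
  trace <- data.frame(sweep = trace_sweep, feature = trace_feat,
                      name = vapply(fs$features, `[[`, character(1),
                                    "name")[trace_feat],
                      variables = vars_of[trace_feat],
                      gain = trace_gain)
  structure(list(
    features = fs, lambda = lambda, beta = beta, log_z = lz,
    entropy = entropy, trace = trace, presence_means = fbar,
    n_presence = m, n_background = B,
    add_samples_to_background = add_samples_to_background,
    converged = sweep < max_iter, n_sweeps = sweep,
    objective = obj, beta_multiplier = beta_multiplier),
    class = "maxent_model")
}

soft_threshold <- function(z, g) sign(z) * max(0, abs(z) - g)

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "maxent_model: %d features (%d active), %d presences vs %d background\n",
    length(x$lambda), sum(x$lambda != 0), x$n_presence, x$n_background))
  cat(sprintf("  entropy %.4f, %s after %d sweeps, penalized nll %.5f\n",
              x$entropy,
              if (x$converged) "converged" else "iteration cap reached",
              x$n_sweeps, x$objective))
  invisible(x)
}

# Raw variable matrix for prediction input: accepts a matrix/data.frame of
# raw predictors or an env_stack (cells in row-major order, NA at joint
# nodata).
prediction_matrix <- function(model, newdata) {
  if (inherits(newdata, "env_stack")) {
    X <- vapply(newdata$layers, function(l) as.vector(t(l$values)),
                numeric(newdata$spec$n_rows * newdata$spec$n_cols))
    colnames(X) <- names(newdata$layers)
    return(X)
  }
  as.matrix(newdata)
}

#' Predict raw (Gibbs) and logistic suitability
#'
#' Raw scores are `exp(eta(x) - log Z)` with the training normalizer, so
#' the training-background scores sum to 1.  Logistic output is the
#' entropy-calibrated transform `e^H * raw / (1 + e^H * raw)` (default
#' prevalence 0.5): a model with all coefficients zero scores 0.5
#' everywhere.
#'
#' @param model A [maxent_fit()] model.
#' @param newdata Matrix/data.frame of raw predictor values with the
#'   training columns, or an [env_stack()].
#' @return For matrix input, a numeric vector (NA rows propagate NA);
#'   for an [env_stack()], a [raster_grid()] of scores.
#' @export
predict_raw <- function(model, newdata) {
  predict_scores(model, newdata, logistic = FALSE)
}

#' @rdname predict_raw
#' @export
predict_logistic <- function(model, newdata) {
  predict_scores(model, newdata, logistic = TRUE)
}

predict_scores <- function(model, newdata, logistic) {
  is_stack <- inherits(newdata, "env_stack")
  X <- prediction_matrix(model, newdata)
  n <- nrow(X)
  scores <- rep(NA_real_, n)
  ok <- stats::complete.cases(X[, model$features$var_names, drop = FALSE])
  chunk <- 2048L
  idx_ok <- which(ok)
  for (start in seq(1L, length(idx_ok), by = chunk)) {
    ii <- idx_ok[start:min(start + chunk - 1L, length(idx_ok))]
    Fm <- feature_matrix(model$features, X[ii, , drop = FALSE])
    eta <- as.numeric(Fm %*% model$lambda)
    raw <- exp(eta - model$log_z)
    scores[ii] <- if (logistic) {
      r <- exp(model$entropy) * raw
      r / (1 + r)
    } else raw
  }
  if (is_stack) {
    v <- matrix(scores, newdata$spec$n_rows, newdata$spec$n_cols,
                byrow = TRUE)
    return(raster_grid(newdata$spec, v,
                       name = if (logistic) "logistic" else "raw"))
  }
  scores
}

#' Serialize / restore a fitted model as JSON
#'
#' @param model A [maxent_fit()] model.
#' @param path Output/input JSON path.
#' @return `write_model` returns `path` invisibly; `read_model` returns
#'   the restored `maxent_model` (trace summarised to per-feature total
#'   gain).
#' @export
write_model <- function(model, path) {
  obj <- list(
    features = model$features$features,
    var_names = model$features$var_names,
    categorical = as.list(model$features$categorical),
    classes = model$features$classes,
    lambda = model$lambda, beta = model$beta,
    log_z = model$log_z, entropy = model$entropy,
    presence_means = model$presence_means,
    n_presence = model$n_presence, n_background = model$n_background,
    add_samples_to_background = model$add_samples_to_background,
    converged = model$converged, n_sweeps = model$n_sweeps,
    objective = model$objective, beta_multiplier = model$beta_multiplier,
    trace_gain_by_feature = as.list(
      tapply(model$trace$gain, model$trace$feature, sum)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  feats <- lapply(obj$features, function(f) {
    f$vars <- unlist(f$vars)
    f
  })
  fs <- structure(list(features = feats, var_names = obj$var_names,
                       categorical = unlist(obj$categorical),
                       classes = obj$classes),
                  class = "feature_set")
  gain_by_feature <- unlist(obj$trace_gain_by_feature)
  fi <- as.integer(names(gain_by_feature))
  vars_of <- vapply(feats, function(f) paste(f$vars, collapse = "*"),
                    character(1))
  trace <- data.frame(sweep = NA_integer_, feature = fi,
                      name = vapply(feats, `[[`, character(1), "name")[fi],
                      variables = vars_of[fi],
                      gain = as.numeric(gain_by_feature))
  structure(list(features = fs, lambda = obj$lambda, beta = obj$beta,
                 log_z = obj$log_z, entropy = obj$entropy, trace = trace,
                 presence_means = obj$presence_means,
                 n_presence = obj$n_presence,
                 n_background = obj$n_background,
                 add_samples_to_background = obj$add_samples_to_background,
                 converged = obj$converged, n_sweeps = obj$n_sweeps,
                 objective = obj$objective,
                 beta_multiplier = obj$beta_multiplier),
            class = "maxent_model")
}
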