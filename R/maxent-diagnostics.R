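# Variable-importance diagnostics: the percent-contribution heuristic
# (sequential training-gain credit), permutation importance (training-AUC
# drop under column shuffling), and response curves.

#' Percent contribution of each variable
#'
#' Each accepted coordinate-descent step's objective gain is credited to
#' the updated feature's source variable(s) -- split equally for product
#' features -- and the per-variable totals are scaled to sum to 100.
#'
#' @param model A [maxent_fit()] model (its training trace must be
#'   nonempty).
#' @return Data.frame with `variable` and `percent_contribution`, sorted
#'   decreasing; variables with no credited gain appear with 0.
#' @export
percent_contribution <- function(model) {
  tr <- model$trace
  if (nrow(tr) == 0L) stop("model trace is empty; nothing was fitted")
  credit <- stats::setNames(numeric(length(model$features$var_names)),
                            model$features$var_names)
  for (i in seq_len(nrow(tr))) {
    f <- model$features$features[[tr$feature[i]]]
    g <- max(0, tr$gain[i])
    share <- g / length(f$vars)
    for (v in f$vars) credit[v] <- credit[v] + share
  }
  tot <- sum(credit)
  pct <- if (tot > 0) 100 * credit / tot else credit
  out <- data.frame(variable = names(pct),
                    percent_contribution = as.numeric(pct))
  out[order(-out$percent_contribution), , drop = FALSE]
}

#' Permutation importance of each variable
#'
#' For each variable, its raw values are permuted across the combined
#' presence + background rows, model scores are recomputed, and the drop
#' in training ROC AUC from the unpermuted AUC is recorded (floored at
#' 0), averaged over `n_perm` shuffles, then scaled so the importances
#' sum to 100.
#'
#' @param model A [maxent_fit()] model.
#' @param presence,background Raw predictor matrices used in training.
#' @param n_perm Number of permutations per variable (default 5).
#' @param seed Integer seed.
#' @return Data.frame with `variable`, `permutation_importance` (scaled
#'   to sum 100; all-zero if no permutation changes the AUC) and
#'   `auc_drop` (unscaled mean drop), sorted decreasing.
#' @export
permutation_importance <- function(model, presence, background,
                                   n_perm = 5, seed = 1) {
  stopifnot(n_perm >= 1)
  presence <- as.matrix(presence)
  background <- as.matrix(background)
  X <- rbind(presence, background)
  if (nrow(X) < 2L) stop("need at least 2 rows to permute")
  labels <- c(rep(1L, nrow(presence)), rep(0L, nrow(background)))
  base_auc <- roc_auc(predict_raw(model, X), labels)
  vars <- model$features$var_names
  drops <- stats::setNames(numeric(length(vars)), vars)
  with_local_seed(seed, {
    for (v in vars) {
      d <- 0
      for (k in seq_len(n_perm)) {
        Xp <- X
        Xp[, v] <- X[sample.int(nrow(X)), v]
        d <- d + max(0, base_auc - roc_auc(predict_raw(model, Xp), labels))
      }
      drops[v] <- d / n_perm
    }
  })
  tot <- sum(drops)
  imp <- if (tot > 0) 100 * drops / tot else drops
  out <- data.frame(variable = names(imp),
                    permutation_importance = as.numeric(imp),
                    auc_drop = as.numeric(drops))
  out[order(-out$permutation_importance), , drop = FALSE]
}

#' Joint contribution/importance table
#'
#' @inheritParams permutation_importance
#' @return Data.frame with `variable`, `percent_contribution` and
#'   `permutation_importance`, ordered by percent contribution.
#' @export
contribution_table <- function(model, presence, background, n_perm = 5,
                               seed = 1) {
  pc <- if (nrow(model$trace) == 0L) {
    # fully shrunk model: no gain was ever credited
    data.frame(variable = model$features$var_names,
               percent_contribution = 0)
  } else percent_contribution(model)
  pi <- permutation_importance(model, presence, background,
                               n_perm = n_perm, seed = seed)
  out <- merge(pc, pi[, c("variable", "permutation_importance")],
               by = "variable", sort = FALSE)
  out[order(-out$percent_contribution), , drop = FALSE]
}

#' Response curve of one variable
#'
#' Logistic output along a grid of values of one variable, all other
#' variables held at their background means.
#'
#' @param model A [maxent_fit()] model.
#' @param variable Variable name.
#' @param background Raw background predictor matrix (supplies the means
#'   and the default value grid).
#' @param values Optional value grid; defaults to 100 points spanning the
#'   background range (or `c(0, 1)` for a binary variable).
#' @return Data.frame with `value` and `logistic`.
#' @export
response_curve <- function(model, variable, background, values = NULL) {
  vars <- model$features$var_names
  if (!variable %in% vars) stop("unknown variable ", variable)
  background <- as.matrix(background)
  if (is.null(values)) {
    x <- background[, variable]
    values <- if (isTRUE(model$features$categorical[[variable]]))
      sort(unique(x))
    else seq(min(x), max(x), length.out = 100)
  }
  X <- matrix(rep(colMeans(background[, vars, drop = FALSE]),
                  each = length(values)),
              nrow = length(values),
              dimnames = list(NULL, vars))
  X[, variable] <- values
  data.frame(value = values, logistic = predict_logistic(model, X))
}
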