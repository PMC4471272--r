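# Independent oracles and small fixtures shared across tests.  Each
# oracle is a deliberately naive implementation kept separate from the
# package's code path.

# ROC AUC by exhaustive presence-absence pair counting (win = 1, tie = 1/2).
oracle_auc <- function(scores, labels) {
  p <- scores[labels == 1]
  a <- scores[labels == 0]
  tot <- 0
  for (x in p) for (y in a)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(p) * length(a))
}

# Maximum independent set size of a conflict graph by brute force over
# all subsets (n <= ~15).
oracle_mis <- function(conflict) {
  n <- nrow(conflict)
  best <- 0
  for (code in 0:(2^n - 1)) {
    members <- which(bitwAnd(code, 2^(0:(n - 1))) > 0)
    if (length(members) <= best) next
    ok <- TRUE
    if (length(members) > 1) {
      pr <- utils::combn(members, 2)
      for (k in seq_len(ncol(pr)))
        if (conflict[pr[1, k], pr[2, k]]) { ok <- FALSE; break }
    }
    if (ok) best <- length(members)
  }
  best
}

# Great-circle distance by the spherical law of cosines (km).
oracle_sloc_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  d <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  6371.0088 * acos(pmin(1, pmax(-1, d)))
}

# Tiny landscape + data bundle used by several tests.
tiny_spec <- function() grid_spec(-76, -73, -2, 3, cell_size = 0.25)

tiny_config <- function(delta = 1, seed = 1) {
  cfg <- default_config(delta = delta, seed = seed, cell_size = 0.3)
  cfg$n_layers <- 6
  cfg$target_cells <- 80
  cfg$n_occurrences <- 120
  cfg$n_sites <- 60
  cfg$n_resource <- 50
  cfg$thin_reps <- 10
  cfg$n_background <- 150
  cfg$n_perm <- 2
  cfg
}

# Small presence/background predictor matrices with one informative and
# one noise variable.
toy_pb <- function(seed = 1, m = 60, b = 120) {
  set.seed(seed)
  bg <- cbind(x = stats::rnorm(b), noise = stats::rnorm(b))
  pr <- cbind(x = stats::rnorm(m, mean = 1.2, sd = 0.6),
              noise = stats::rnorm(m))
  list(presence = pr, background = bg)
}
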