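# Independent oracles used across the test files.

# Spearman via the explicit rank formula (tie-free vectors only).
spearman_rank_formula <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Exhaustive Otsu: try every candidate cut and minimise the within-class
# variance directly.
otsu_brute_force <- function(v) {
  v <- as.numeric(v)
  cands <- sort(unique(v))
  cands <- cands[-length(cands)]
  pop_ss <- function(z) if (length(z) > 1) sum((z - mean(z))^2) else 0
  wcv <- vapply(cands, function(t) {
    (pop_ss(v[v <= t]) + pop_ss(v[v > t])) / length(v)
  }, numeric(1))
  cands[which.min(wcv)]
}

# Within-class variance at a given cut (for comparing tied optima).
otsu_objective <- function(v, t) {
  v <- as.numeric(v)
  pop_ss <- function(z) if (length(z) > 1) sum((z - mean(z))^2) else 0
  (pop_ss(v[v <= t]) + pop_ss(v[v > t])) / length(v)
}

# OLS through the explicit normal equations.
ols_normal_equations <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# All permutations of a vector (exhaustive oracle input).
combinat_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(combinat_perms(v[-i]), function(p) c(v[i], p))
  }))
}

# Homogeneous Bernoulli residue mask.
random_mask <- function(p, nrow_px, ncol_px) {
  matrix(stats::runif(nrow_px * ncol_px) < p, nrow_px, ncol_px)
}

# Small survey config for fast tests.
small_config <- function(seed = 1L, n_plots = 40L, ...) {
  generator_config(n_households = 25L, n_plots = n_plots,
                   m5_n = min(30L, n_plots), m6_n = min(35L, n_plots),
                   seed = seed, ...)
}
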