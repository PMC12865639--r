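# Independent oracles used across the suite. Each implements the definition
# directly (loops, closed forms, exhaustive enumeration), never the package's
# own code path.

# Weighted Pearson correlation straight from the weighted-moment definition.
oracle_weighted_pearson <- function(x, y, w) {
  xb <- 0; yb <- 0; sw <- 0
  for (i in seq_along(x)) {
    xb <- xb + w[i] * x[i]; yb <- yb + w[i] * y[i]; sw <- sw + w[i]
  }
  xb <- xb / sw; yb <- yb / sw
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_along(x)) {
    sxy <- sxy + w[i] * (x[i] - xb) * (y[i] - yb)
    sxx <- sxx + w[i] * (x[i] - xb)^2
    syy <- syy + w[i] * (y[i] - yb)^2
  }
  sxy / sqrt(sxx * syy)
}

# Weighted least squares by direct solution of the 2x2 normal equations.
oracle_wls_coef <- function(x, y, w) {
  A <- matrix(c(sum(w), sum(w * x), sum(w * x), sum(w * x^2)), 2, 2)
  b <- c(sum(w * y), sum(w * x * y))
  solve(A, b) # (intercept, slope)
}

# All permutations of a vector (exhaustive; for tiny n only).
all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

# Exact two-sided permutation p for Spearman's rho by full enumeration.
oracle_spearman_perm <- function(x, y) {
  obs <- stats::cor(rank(x), rank(y))
  rs <- vapply(all_perms(y), function(p) stats::cor(rank(x), rank(p)),
               numeric(1))
  list(rho = obs, p = mean(abs(rs) >= abs(obs) - 1e-12))
}

# A small complete trial set with hand-set hazard ratios, for deterministic
# plumbing tests that should not depend on the generator.
toy_trial_set <- function(n = 6, seed = 99) {
  gen <- generate_trials(synthetic_config(n_trials = n, seed = seed))
  gen$trials
}

# Path to a user-transcribed supplementary HR extraction table, if present.
extraction_table_or_null <- function() {
  p <- system.file("extdata", "extraction_hr_table.csv", package = "pfs2surr")
  if (nzchar(p) && file.exists(p)) read_trials(p) else NULL
}

fail_no_extraction <- function() {
  testthat::fail(paste(
    "the published per-trial hazard ratios exist only in the journal's",
    "supplementary appendix and are not redistributable here; transcribe",
    "them into inst/extdata/extraction_hr_table.csv (schema: trial_columns())",
    "to enable this check"
  ))
}
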