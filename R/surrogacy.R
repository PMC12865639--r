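# Trial-level surrogacy engine.
#
# The model is a sample-size-weighted least-squares regression of treatment
# effects on the true endpoint on treatment effects on the surrogate,
#
#     log(HR_OS) = beta0 + beta1 * log(HR_PFS2) + epsilon,
#
# with each trial weighted by its total number of randomized patients.
# Natural logarithms are used throughout; the base cancels in r and R^2 and
# only rescales the slope. Association strength is summarized by the weighted
# Pearson correlation r with a percentile-bootstrap 95% CI, and by
# R^2 = r^2, the share of between-trial variance in the OS effect explained
# by the surrogate effect (R^2 >= 0.7 is the conventional trial-level
# surrogacy threshold in oncology).

#' Sample-size-weighted Pearson correlation
#'
#' Computes the weighted product-moment correlation
#' \deqn{r_w = \frac{\sum w_i (x_i-\bar x_w)(y_i-\bar y_w)}
#'   {\sqrt{\sum w_i (x_i-\bar x_w)^2 \sum w_i (y_i-\bar y_w)^2}}}
#' with weighted means \eqn{\bar x_w = \sum w_i x_i / \sum w_i}. The result is
#' invariant to rescaling all weights by a positive constant and reduces to
#' the ordinary Pearson correlation under equal weights.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @param w Positive weights (total randomized patients, in the intended use).
#' @return Weighted correlation in [-1, 1].
#' @export
weighted_pearson <- function(x, y, w = rep(1, length(x))) {
  n <- length(x)
  stopifnot(length(y) == n, length(w) == n, n >= 2)
  if (anyNA(x) || anyNA(y) || anyNA(w)) stop("missing values in input")
  if (any(w <= 0)) stop("weights must be strictly positive")
  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - xb)^2)
  syy <- sum(w * (y - yb)^2)
  if (sxx <= 0 || syy <= 0) {
    stop("degenerate input: zero weighted variance in x or y")
  }
  r <- sum(w * (x - xb) * (y - yb)) / sqrt(sxx * syy)
  max(-1, min(1, r))
}

#' Weighted least-squares fit of the surrogacy line
#'
#' Solves the weighted normal equations for \eqn{(\beta_0, \beta_1)}
#' minimizing \eqn{\sum w_i (y_i - \beta_0 - \beta_1 x_i)^2}. The slope
#' standard error uses the weighted residual variance on n - 2 degrees of
#' freedom; the slope p-value is a two-sided t-test. `r2` is the weighted
#' coefficient of determination, identically the square of
#' [weighted_pearson()] on the same points and weights.
#'
#' @inheritParams weighted_pearson
#' @return Object of class `wls_fit`: list with `slope`, `intercept`,
#'   `slope_se`, `slope_p`, `r2`, `n`, `residuals`, `fitted`.
#' @export
wls_fit <- function(x, y, w = rep(1, length(x))) {
  n <- length(x)
  stopifnot(length(y) == n, length(w) == n)
  if (n < 3) stop("insufficient trials: need >= 3, got ", n)
  if (anyNA(x) || anyNA(y) || anyNA(w)) stop("missing values in input")
  if (any(w <= 0)) stop("weights must be strictly positive")
  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - xb)^2)
  if (sxx <= 0) stop("degenerate input: zero weighted variance in x")
  sxy <- sum(w * (x - xb) * (y - yb))
  syy <- sum(w * (y - yb)^2)
  slope <- sxy / sxx
  intercept <- yb - slope * xb
  fitted <- intercept + slope * x
  res <- y - fitted
  rss <- sum(w * res^2)
  # sigma^2 and sxx scale together in w, so se and p are weight-scale invariant
  sigma2 <- rss / (n - 2)
  slope_se <- sqrt(sigma2 / sxx)
  tstat <- slope / slope_se
  slope_p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  r2 <- if (syy > 0) 1 - rss / syy else 0
  r2 <- max(0, min(1, r2))
  structure(
    list(
      slope = slope, intercept = intercept, slope_se = slope_se,
      slope_p = slope_p, r2 = r2, n = n, residuals = res, fitted = fitted
    ),
    class = "wls_fit"
  )
}

#' Percentile-bootstrap CI for the weighted correlation
#'
#' Resamples trials (x, y, w triples jointly) with replacement, recomputes
#' the weighted Pearson correlation per replicate, and returns percentile
#' bounds. Replicates with zero weighted variance (e.g. a single distinct
#' trial drawn n times) are discarded and counted. Bounds are clamped to
#' [-1, 1]; results are deterministic for a fixed seed and independent of the
#' row order the caller happens to use, provided rows are pre-sorted (as
#' [run_surrogacy()] does by trial id).
#'
#' @inheritParams weighted_pearson
#' @param n_boot Number of bootstrap replicates (>= 200; default 2000).
#' @param seed Integer seed, mandatory.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return List with `low`, `high`, `n_dropped` (degenerate replicates) and
#'   `replicates` (the retained bootstrap correlations).
#' @export
bootstrap_r_ci <- function(x, y, w = rep(1, length(x)), n_boot = 2000,
                           seed, level = 0.95) {
  n <- length(x)
  stopifnot(length(y) == n, length(w) == n, level > 0, level < 1)
  if (n < 3) stop("insufficient trials: need >= 3, got ", n)
  if (missing(seed)) stop("an explicit seed is required")
  if (n_boot < 200) warning("n_boot < 200 gives unstable percentile bounds")
  idx <- local_seed(seed, matrix(
    sample.int(n, n * n_boot, replace = TRUE), nrow = n, ncol = n_boot
  ))
  rs <- apply(idx, 2, function(i) {
    wi <- w[i]; xi <- x[i]; yi <- y[i]
    xb <- sum(wi * xi) / sum(wi)
    yb <- sum(wi * yi) / sum(wi)
    sxx <- sum(wi * (xi - xb)^2)
    syy <- sum(wi * (yi - yb)^2)
    if (sxx <= 0 || syy <= 0) return(NA_real_)
    sum(wi * (xi - xb) * (yi - yb)) / sqrt(sxx * syy)
  })
  dropped <- sum(is.na(rs))
  rs <- rs[!is.na(rs)]
  if (length(rs) == 0) stop("all bootstrap replicates degenerate")
  alpha <- (1 - level) / 2
  qs <- unname(stats::quantile(rs, c(alpha, 1 - alpha), names = FALSE))
  list(
    low = max(-1, min(1, qs[1])),
    high = max(-1, min(1, qs[2])),
    n_dropped = dropped,
    replicates = rs
  )
}

#' Correlation strength band
#'
#' Classifies a correlation coefficient using the thresholds common in
#' clinical-medicine research: r < 0.5 poor to fair, 0.5 <= r <= 0.7
#' moderate, r > 0.7 strong. Bands apply to the signed r (no absolute value),
#' so strongly negative correlations report `poor_fair`; callers should flag
#' negative r separately.
#'
#' @param r Correlation in [-1, 1].
#' @return One of `"poor_fair"`, `"moderate"`, `"strong"`.
#' @export
strength_band <- function(r) {
  stopifnot(is.numeric(r), length(r) == 1, !is.na(r), r >= -1, r <= 1)
  if (r < 0.5) "poor_fair" else if (r <= 0.7) "moderate" else "strong"
}

#' IQWiG surrogate-validity classification
#'
#' Applies the IQWiG rule to the 95% CI of the correlation: the surrogate is
#' `valid` if the lower bound is >= 0.85, `invalid` if the upper bound is
#' <= 0.70, and `inconclusive` otherwise.
#'
#' @param ci_low,ci_high CI bounds with `ci_low <= ci_high`.
#' @return One of `"valid"`, `"inconclusive"`, `"invalid"`.
#' @export
iqwig_classify <- function(ci_low, ci_high) {
  stopifnot(is.numeric(ci_low), is.numeric(ci_high), ci_low <= ci_high)
  if (ci_low >= 0.85) "valid" else if (ci_high <= 0.70) "invalid" else "inconclusive"
}

.endpoint_column <- function(endpoint) {
  endpoint <- match.arg(endpoint, .hr_endpoints)
  paste0("hr_", endpoint)
}

#' Run one trial-level surrogacy analysis
#'
#' Composes the engine: selects trials with both endpoints reported, takes
#' natural logs of the hazard ratios, weights by total randomized patients
#' (or equally), fits the weighted regression, computes the weighted Pearson
#' correlation with its percentile-bootstrap CI, and classifies the result by
#' strength band and IQWiG validity. Trials are sorted by `trial_id` before
#' bootstrap resampling so results do not depend on input row order.
#'
#' @param trials A `trial_set`.
#' @param x_endpoint,y_endpoint Endpoint labels among `"pfs1"`, `"pfs2"`,
#'   `"os_initial"`, `"os_longterm"` (surrogate on x, true endpoint on y).
#' @param weighting `"total_n"` (default) or `"equal"`.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @param level CI level (default 0.95).
#' @param quiet Suppress exclusion messages.
#' @return Object of class `surrogacy_result`: n, trial ids, x/y/w vectors,
#'   `fit` (the [wls_fit()]), `r`, `r_ci_low`, `r_ci_high`, `r2`, `strength`,
#'   `iqwig`, bookkeeping (`n_boot`, `seed`, `weights` label, dropped
#'   replicate count), and `negative_r` flag.
#' @export
run_surrogacy <- function(trials, x_endpoint = "pfs2",
                          y_endpoint = "os_initial",
                          weighting = c("total_n", "equal"),
                          n_boot = 2000, seed = 1L, level = 0.95,
                          quiet = FALSE) {
  weighting <- match.arg(weighting)
  xcol <- .endpoint_column(x_endpoint)
  ycol <- .endpoint_column(y_endpoint)
  sub <- analysis_subset(trials, unique(c(xcol, ycol)), min_n = 3,
                         quiet = quiet)
  sub <- sub[order(sub$trial_id), , drop = FALSE]
  x <- log(as.numeric(sub[[xcol]]))
  y <- log(as.numeric(sub[[ycol]]))
  w <- if (weighting == "total_n") total_n(sub) else rep(1, nrow(sub))
  fit <- wls_fit(x, y, w)
  r <- weighted_pearson(x, y, w)
  ci <- bootstrap_r_ci(x, y, w, n_boot = n_boot, seed = seed, level = level)
  structure(
    list(
      n = nrow(sub), trial_ids = sub$trial_id,
      x_endpoint = x_endpoint, y_endpoint = y_endpoint,
      x = x, y = y, w = w,
      fit = fit, r = r, r_ci_low = ci$low, r_ci_high = ci$high,
      r2 = fit$r2, strength = strength_band(r),
      iqwig = iqwig_classify(ci$low, ci$high),
      negative_r = r < 0,
      n_boot = n_boot, seed = as.integer(seed), level = level,
      weights = weighting, n_dropped_replicates = ci$n_dropped
    ),
    class = "surrogacy_result"
  )
}

#' @export
print.surrogacy_result <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Trial-level surrogacy: log(HR %s) ~ log(HR %s), %d trials, %s weights\n",
    x$y_endpoint, x$x_endpoint, x$n, x$weights
  ))
  cat(sprintf(
    "  weighted r = %s (95%% CI %s to %s), R2 = %s\n",
    format(round(x$r, digits)), format(round(x$r_ci_low, digits)),
    format(round(x$r_ci_high, digits)), format(round(x$r2, digits))
  ))
  cat(sprintf(
    "  slope = %s (SE %s, p = %s), intercept = %s\n",
    format(signif(x$fit$slope, digits)), format(signif(x$fit$slope_se, digits)),
    format(signif(x$fit$slope_p, digits)), format(signif(x$fit$intercept, digits))
  ))
  cat(sprintf("  strength: %s%s; IQWiG validity: %s\n",
              x$strength,
              if (isTRUE(x$negative_r)) " (NEGATIVE correlation)" else "",
              x$iqwig))
  invisible(x)
}

# Flat one-row summary used by report rendering and stratified tables.
summarize_result <- function(res, label = NA_character_) {
  data.frame(
    analysis = label, n = res$n, r = res$r,
    r_ci_low = res$r_ci_low, r_ci_high = res$r_ci_high, r2 = res$r2,
    slope = res$fit$slope, intercept = res$fit$intercept,
    slope_p = res$fit$slope_p, strength = res$strength, iqwig = res$iqwig,
    stringsAsFactors = FALSE
  )
}
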