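test_that("weighted Pearson matches its definition and limiting cases", {
  # frozen brute-force value of the weighted-moment formula
  x <- c(0.1, -0.2, 0.05, -0.4)
  y <- c(0.05, -0.1, 0.1, -0.3)
  w <- c(100, 200, 300, 400)
  expect_equal(weighted_pearson(x, y, w), 0.986750066212708,
               tolerance = 1e-10)
  expect_equal(weighted_pearson(x, y, w), oracle_weighted_pearson(x, y, w),
               tolerance = 1e-12)

  set.seed(11)
  for (rep in 1:20) {
    n <- sample(4:30, 1)
    xs <- rnorm(n); ys <- 0.4 * xs + rnorm(n); ws <- runif(n, 1, 1000)
    # equal weights reduce to ordinary Pearson
    expect_equal(weighted_pearson(xs, ys, rep(2.5, n)), cor(xs, ys),
                 tolerance = 1e-12)
    # brute-force oracle on random weighted inputs
    expect_equal(weighted_pearson(xs, ys, ws),
                 oracle_weighted_pearson(xs, ys, ws), tolerance = 1e-12)
    # weight-scale invariance
    expect_equal(weighted_pearson(xs, ys, ws * 173.4),
                 weighted_pearson(xs, ys, ws), tolerance = 1e-12)
  }

  # perfect collinearity
  xs <- rnorm(8)
  expect_equal(weighted_pearson(xs, 2 * xs + 1, runif(8, 1, 9)), 1)
  # degenerate variance errors rather than silently returning 0
  expect_error(weighted_pearson(rep(1, 5), rnorm(5), rep(1, 5)), "degenerate")
  expect_error(weighted_pearson(rnorm(5), rnorm(5), c(-1, 1, 1, 1, 1)),
               "positive")
})

test_that("weighted least squares solves the normal equations", {
  # frozen hand solution of the 2x2 weighted normal equations
  fit <- wls_fit(c(-1, 0, 1), c(0, 0, 1), c(1, 1, 2))
  expect_equal(fit$slope, 6 / 11, tolerance = 1e-10)
  expect_equal(fit$intercept, 4 / 11, tolerance = 1e-10)

  set.seed(22)
  for (rep in 1:15) {
    n <- sample(5:40, 1)
    xs <- rnorm(n); ys <- 0.3 - 0.6 * xs + rnorm(n, 0, 0.5)
    ws <- runif(n, 0.5, 500)
    fit <- wls_fit(xs, ys, ws)
    # closed-form normal-equation oracle
    ab <- oracle_wls_coef(xs, ys, ws)
    expect_equal(fit$intercept, ab[1], tolerance = 1e-10)
    expect_equal(fit$slope, ab[2], tolerance = 1e-10)
    # R^2 is identically the squared weighted Pearson correlation
    expect_equal(fit$r2, weighted_pearson(xs, ys, ws)^2, tolerance = 1e-10)
    expect_equal(sign(fit$slope), sign(weighted_pearson(xs, ys, ws)))
    # the full fit agrees with the lm(weights=) cross-check
    lmfit <- summary(lm(ys ~ xs, weights = ws))
    expect_equal(fit$slope_se, lmfit$coefficients["xs", "Std. Error"],
                 tolerance = 1e-10)
    expect_equal(fit$slope_p, lmfit$coefficients["xs", "Pr(>|t|)"],
                 tolerance = 1e-10)
    expect_equal(fit$r2, lmfit$r.squared, tolerance = 1e-10)
    # weight-scale invariance of every reported quantity
    fit2 <- wls_fit(xs, ys, ws * 997)
    for (f in c("slope", "intercept", "slope_se", "slope_p", "r2")) {
      expect_equal(fit2[[f]], fit[[f]], tolerance = 1e-12)
    }
    # equal weights agree with textbook OLS
    olsfit <- summary(lm(ys ~ xs))
    efit <- wls_fit(xs, ys, rep(1, n))
    expect_equal(efit$slope, unname(coef(lm(ys ~ xs))[2]), tolerance = 1e-10)
    expect_equal(efit$r2, olsfit$r.squared, tolerance = 1e-10)
  }

  # exact line and constant-response edge cases
  xs <- c(-2, 0, 1, 3)
  exact <- wls_fit(xs, -0.5 * xs, c(1, 1, 1, 1))
  expect_equal(exact$slope, -0.5, tolerance = 1e-12)
  expect_equal(exact$intercept, 0, tolerance = 1e-12)
  expect_equal(exact$r2, 1, tolerance = 1e-10)
  flat <- wls_fit(xs, rep(2, 4), c(1, 2, 3, 4))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r2, 0)

  expect_error(wls_fit(1:2, 1:2, c(1, 1)), "insufficient trials")
  expect_error(wls_fit(rep(1, 4), rnorm(4), rep(1, 4)), "degenerate")
})

test_that("hazard-ratio inversion reflects the regression as the algebra requires", {
  # h -> 1/h on both endpoints maps (x, y) to (-x, -y): the slope is
  # unchanged, the intercept is negated, and r and R^2 are untouched
  set.seed(33)
  hx <- exp(rnorm(12, -0.3, 0.3)); hy <- exp(rnorm(12, -0.2, 0.3))
  w <- runif(12, 100, 900)
  a <- wls_fit(log(hx), log(hy), w)
  b <- wls_fit(log(1 / hx), log(1 / hy), w)
  expect_equal(b$slope, a$slope, tolerance = 1e-12)
  expect_equal(b$intercept, -a$intercept, tolerance = 1e-12)
  expect_equal(b$r2, a$r2, tolerance = 1e-12)
  expect_equal(weighted_pearson(log(1 / hx), log(1 / hy), w),
               weighted_pearson(log(hx), log(hy), w), tolerance = 1e-12)
})

test_that("percentile bootstrap is deterministic, clamped, and handles collinearity", {
  set.seed(44)
  xs <- rnorm(10); ys <- 0.5 * xs + rnorm(10, 0, 0.3); ws <- runif(10, 1, 10)
  ci1 <- bootstrap_r_ci(xs, ys, ws, n_boot = 500, seed = 7)
  ci2 <- bootstrap_r_ci(xs, ys, ws, n_boot = 500, seed = 7)
  expect_identical(ci1[c("low", "high")], ci2[c("low", "high")])
  expect_lte(ci1$low, ci1$high)
  expect_gte(ci1$low, -1); expect_lte(ci1$high, 1)

  # perfectly collinear data: every non-degenerate replicate gives r = 1
  cl <- bootstrap_r_ci(xs, 3 * xs - 1, ws, n_boot = 300, seed = 7)
  expect_equal(cl$low, 1); expect_equal(cl$high, 1)

  # tiny-n weak-signal subgroups can span the whole [-1, 1] range
  tiny <- bootstrap_r_ci(c(-0.1, 0.05, 0.2), c(0.3, -0.2, 0.25),
                         c(200, 300, 250), n_boot = 2000, seed = 7)
  expect_equal(tiny$low, -1); expect_equal(tiny$high, 1)
  expect_gt(tiny$n_dropped, 0) # single-trial replicates are degenerate

  expect_warning(bootstrap_r_ci(xs, ys, ws, n_boot = 100, seed = 1),
                 "n_boot")
  expect_error(bootstrap_r_ci(xs, ys, ws, n_boot = 500), "seed")
})

test_that("bootstrap CI coverage of the true correlation is sane and seed-stable", {
  # Coverage is assessed against the population correlation of the generating
  # model, beta1*tau / sqrt(beta1^2 tau^2 + sigma^2), in the low-estimation-
  # noise regime where the observed-scale correlation is not attenuated.
  # Percentile bootstrap at n = 15 is expected to sit a little below the
  # nominal 95%; the check is calibration sanity, not exact nominal coverage.
  derive_seed <- pfs2surr:::derive_seed
  rho_pop <- 0.53 * 0.25 / sqrt((0.53 * 0.25)^2 + 0.13^2)
  coverage_run <- function(master_seed, n_rep = 150) {
    covered <- logical(n_rep)
    for (k in seq_len(n_rep)) {
      cfg <- synthetic_config(n_trials = 15, n_range = c(2000, 4000),
                              os_maturity_range = c(0.85, 0.95),
                              pfs2_maturity_range = c(0.85, 0.95),
                              seed = derive_seed(master_seed, k))
      tr <- generate_trials(cfg)$trials
      x <- log(tr$hr_pfs2); y <- log(tr$hr_os_initial); w <- total_n(tr)
      ci <- bootstrap_r_ci(x, y, w, n_boot = 400,
                           seed = derive_seed(master_seed, 100000 + k))
      covered[k] <- ci$low <= rho_pop && rho_pop <= ci$high
    }
    mean(covered)
  }
  c1 <- coverage_run(2024)
  c2 <- coverage_run(4048)
  expect_gte(c1, 0.85); expect_lte(c1, 0.995)
  expect_gte(c2, 0.85); expect_lte(c2, 0.995)
  expect_lt(abs(c1 - c2), 0.12) # two-seed reproducibility within MC noise
})

test_that("strength bands and IQWiG validity follow the published rules", {
  expect_equal(strength_band(0.714), "strong")
  expect_equal(strength_band(0.552), "moderate")
  expect_equal(strength_band(0.5), "moderate")
  expect_equal(strength_band(0.7), "moderate")
  expect_equal(strength_band(0.701), "strong")
  expect_equal(strength_band(0.49), "poor_fair")
  expect_equal(strength_band(-0.652), "poor_fair") # signed r, no |r|
  expect_equal(strength_band(-1), "poor_fair")

  expect_equal(iqwig_classify(0.204, 0.893), "inconclusive")
  expect_equal(iqwig_classify(0.86, 0.99), "valid")
  expect_equal(iqwig_classify(0.85, 0.99), "valid")
  expect_equal(iqwig_classify(-0.2, 0.70), "invalid")
  expect_equal(iqwig_classify(0.1, 0.71), "inconclusive")
  expect_error(iqwig_classify(0.9, 0.2))
})

test_that("run_surrogacy composes the engine and is order- and self-consistent", {
  trials <- toy_trial_set(n = 12, seed = 6)
  res <- run_surrogacy(trials, seed = 5, n_boot = 500, quiet = TRUE)
  expect_s3_class(res, "surrogacy_result")
  expect_equal(res$r2, res$r^2, tolerance = 1e-10)
  expect_equal(res$strength, strength_band(res$r))
  expect_equal(res$iqwig, iqwig_classify(res$r_ci_low, res$r_ci_high))
  expect_equal(res$n, 12)

  # shuffling input rows changes nothing (rows are sorted before resampling)
  shuf <- trials[sample(nrow(trials)), ]
  res2 <- run_surrogacy(as_trial_set(as.data.frame(shuf)), seed = 5,
                        n_boot = 500, quiet = TRUE)
  expect_equal(res2[setdiff(names(res2), "trial_ids")],
               res[setdiff(names(res), "trial_ids")])

  # x_endpoint == y_endpoint is perfect self-correlation
  self <- run_surrogacy(trials, "pfs2", "pfs2", seed = 5, n_boot = 300,
                        quiet = TRUE)
  expect_equal(self$r, 1)
  expect_equal(self$fit$slope, 1, tolerance = 1e-12)
  expect_equal(self$fit$intercept, 0, tolerance = 1e-12)

  # equal weighting equals the unweighted textbook analysis
  eq <- run_surrogacy(trials, weighting = "equal", seed = 5, n_boot = 300,
                      quiet = TRUE)
  ord <- order(trials$trial_id)
  expect_equal(eq$r, cor(log(trials$hr_pfs2), log(trials$hr_os_initial)),
               tolerance = 1e-12)
  expect_error(run_surrogacy(trials[1:2, ], quiet = TRUE), "insufficient")
})
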