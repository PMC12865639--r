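test_that("Spearman correlation matches the exhaustive permutation oracle", {
  s <- spearman_rho(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(s$rho, 0.8, tolerance = 1e-12)
  expect_equal(s$p, 2 / 15, tolerance = 1e-12) # frozen exact permutation p

  set.seed(55)
  for (rep in 1:5) {
    xs <- sample(1:7); ys <- rnorm(7)
    o <- oracle_spearman_perm(xs, ys)
    s <- spearman_rho(xs, ys)
    expect_equal(s$rho, o$rho, tolerance = 1e-12)
    expect_equal(s$p, o$p, tolerance = 1e-10)
  }

  # strictly monotone pairing and monotone-transform invariance
  expect_equal(spearman_rho(1:6, c(2, 5, 7, 8, 20, 21))$rho, 1)
  xs <- rnorm(12); ys <- 0.7 * xs + rnorm(12, 0, 0.4)
  base <- spearman_rho(xs, ys)
  maps <- list(function(v) exp(v), function(v) v^3, function(v) atan(v) * 5)
  for (f in maps) {
    expect_equal(spearman_rho(f(xs), ys)$rho, base$rho, tolerance = 1e-12)
    expect_equal(spearman_rho(xs, f(ys))$rho, base$rho, tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), rnorm(5)), "degenerate")
})

test_that("arm-level observations and median PFS2/OS ratio summaries", {
  df <- as.data.frame(table1_fixture())[1:3, ]
  df$median_pfs2_int <- c(12, 15, NA)
  df$median_os_int <- c(30, 30, 40)
  df$median_pfs2_ctrl <- c(18, 12.5, 10)
  df$median_os_ctrl <- c(30, 25, 25)
  trials <- as_trial_set(df)
  obs <- arm_observations(trials)
  expect_equal(nrow(obs), 5) # one intervention arm lacks PFS2
  expect_equal(obs$ratio[obs$arm == "control"], c(0.6, 0.5, 0.4))

  # ratios (0.4, 0.5, 0.6): central by direct sort; ties at 0.50 are not
  # counted as "earlier half"
  ctrl <- median_ratio_summary(obs, "control")
  expect_equal(ctrl$central, 0.5)
  expect_equal(c(ctrl$min, ctrl$max), c(0.4, 0.6))
  expect_equal(ctrl$n_below_half, 1)
  expect_gte(ctrl$central, ctrl$min); expect_lte(ctrl$central, ctrl$max)

  # a single arm with median PFS2 equal to median OS
  one <- df[1, ]; one$median_pfs2_int <- 30; one$median_os_int <- 30
  one$median_pfs2_ctrl <- NA
  s <- median_ratio_summary(arm_observations(as_trial_set(one)),
                            "intervention")
  expect_equal(unlist(s[c("central", "min", "max")]),
               c(central = 1, min = 1, max = 1))

  # PFS2 exceeding OS is kept but flagged
  bad <- df[1, ]; bad$median_pfs2_int <- 45; bad$median_os_int <- 30
  expect_warning(arm_observations(as_trial_set(bad)), "exceeding")

  # pooled arm-level correlation across a generated set
  gen <- generate_trials(synthetic_config(n_trials = 10, seed = 12))
  corr <- arm_median_correlation(gen$trials)
  expect_equal(corr$n_arms, 20)
  expect_gt(corr$rho, 0) # medians derive from the same latent effects
})

test_that("drift analysis recovers the attenuation sign and handles no-drift", {
  # strong crossover attenuation, low noise: greater PFS2 benefit (more
  # negative log HR) must associate with larger upward OS drift
  cfg <- synthetic_config(
    n_trials = 12, seed = 9, sigma = 0.05, longterm_fraction = 1,
    crossover_range = c(30, 48), crossover_attenuation = 1,
    n_range = c(2000, 4000), os_maturity_range = c(0.85, 0.95),
    os_maturity_longterm_range = c(0.9, 0.95),
    pfs2_maturity_range = c(0.85, 0.95)
  )
  gen <- generate_trials(cfg)
  d <- drift_analysis(gen$trials, quiet = TRUE)
  expect_equal(d$n, 12)
  expect_lt(d$rho, 0)
  expect_equal(
    d$observations$delta_log_hr_os,
    log(gen$trials$hr_os_longterm) - log(gen$trials$hr_os_initial)
  )

  # identical long-term and initial HRs: all deltas exactly zero -> no drift
  df <- as.data.frame(gen$trials)
  df$hr_os_longterm <- df$hr_os_initial
  df$hr_os_longterm_low <- df$hr_os_initial_low
  df$hr_os_longterm_high <- df$hr_os_initial_high
  expect_error(drift_analysis(as_trial_set(df), quiet = TRUE), "no drift")

  expect_error(drift_analysis(gen$trials[1:2, ], quiet = TRUE),
               "insufficient")
})

test_that("long-term validation mirrors the primary analysis contracts", {
  cfg <- synthetic_config(n_trials = 14, seed = 13, longterm_fraction = 0.6,
                          crossover_attenuation = 0.8)
  trials <- generate_trials(cfg)$trials
  v <- validation_longterm(trials, seed = 6, n_boot = 400, quiet = TRUE)
  expect_equal(v$y_endpoint, "os_longterm")
  expect_equal(v$n, sum(!is.na(trials$hr_os_longterm)))

  # with long-term HRs set equal to initial ones the two analyses coincide
  df <- as.data.frame(trials)
  df$hr_os_longterm <- df$hr_os_initial
  df$hr_os_longterm_low <- df$hr_os_initial_low
  df$hr_os_longterm_high <- df$hr_os_initial_high
  same <- as_trial_set(df)
  a <- validation_longterm(same, seed = 6, n_boot = 400, quiet = TRUE)
  b <- run_surrogacy(same, "pfs2", "os_initial", seed = 6, n_boot = 400,
                     quiet = TRUE)
  for (f in c("n", "r", "r_ci_low", "r_ci_high", "r2")) {
    expect_equal(a[[f]], b[[f]])
  }
  expect_equal(a$fit$slope, b$fit$slope)
})

test_that("subtype subsets run the same engine with small-n guards", {
  cfg <- synthetic_config(n_trials = 18, seed = 19)
  trials <- generate_trials(cfg)$trials
  for (st in c("HRpos_HER2neg", "HER2pos", "HER2neg_mixed")) {
    k <- sum(trials$subtype == st)
    if (k >= 4) {
      res <- subtype_subset_analysis(trials, st, seed = 7, n_boot = 400,
                                     quiet = TRUE)
      expect_equal(res$n, k)
      expect_setequal(res$trial_ids, trials$trial_id[trials$subtype == st])
    }
  }
  # exactly 3 trials: result with an insufficient-precision warning
  df <- as.data.frame(trials)
  df$subtype <- c(rep("HER2pos", 3), rep("HRpos_HER2neg", 15))
  expect_warning(
    r3 <- subtype_subset_analysis(as_trial_set(df), "HER2pos", seed = 7,
                                  n_boot = 400, quiet = TRUE),
    "insufficient precision"
  )
  expect_equal(r3$n, 3)
  # 2 trials: hard error
  df$subtype <- c(rep("HER2pos", 2), rep("HRpos_HER2neg", 16))
  expect_error(
    subtype_subset_analysis(as_trial_set(df), "HER2pos", seed = 7,
                            quiet = TRUE),
    "insufficient trials"
  )
})
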