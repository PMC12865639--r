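# Synthetic trial-set generator.
#
# Emulates the statistical structure the surrogacy analysis assumes: latent
# per-trial treatment effects following the linear surrogacy model
#   ln HR_OS* = beta0 + beta1 * ln HR_PFS2* + Normal(0, sigma^2),
# observed through sampling noise scaled to event counts via the standard
# large-sample approximation SE(ln HR) ~= 2 / sqrt(events) for a 1:1 trial
# (used for unbalanced arms too; a documented simplification). Bigger trials
# therefore yield tighter estimates, the rationale for sample-size weighting.
# Marginal characteristics (sample sizes, maturities, information fractions,
# long-term follow-up availability, crossover exposure) default to the spans
# observed across recent breast-cancer RCT reports.

#' Configuration for the synthetic trial generator
#'
#' Ground-truth and nuisance parameters. Defaults reflect the observed spans
#' of recent metastatic breast-cancer RCTs: total N 112-1050 per trial, OS
#' maturity 12.4%-59.5%, PFS2 maturity 27%-82.4%, OS information fraction
#' 24%-157% (above 100% is legitimate), long-term OS available for ~10/18 of
#' trials, control-arm crossover 0%-48%. The effect-model defaults
#' (`beta1 = 0.53`, `tau = 0.25`, `sigma = 0.13`) put the latent trial-level
#' correlation near 0.71, the regime a moderate-to-strong surrogate produces.
#'
#' @param n_trials Number of trials (>= 3).
#' @param beta0 True intercept on the ln-HR scale.
#' @param beta1 True surrogacy slope.
#' @param tau SD of the true ln HR_PFS2 across trials.
#' @param sigma Trial-level residual SD of ln HR_OS given ln HR_PFS2.
#' @param mu_x Mean true ln HR_PFS2 (default log(0.65)).
#' @param n_range Total randomized patients per trial, (low, high).
#' @param os_maturity_range,pfs2_maturity_range Proportions in (0, 1].
#' @param info_fraction_range Information fraction span; may exceed 1.
#' @param os_maturity_longterm_range Long-term OS maturity span.
#' @param longterm_fraction Fraction of trials with long-term OS follow-up.
#' @param crossover_range Control-arm crossover span on the 0-100 scale.
#' @param crossover_attenuation Fraction of the true OS effect lost at
#'   long-term follow-up per unit crossover proportion (0 = none).
#' @param unbalanced_prob Probability a trial randomizes 2:1 instead of 1:1.
#' @param pfs1_gamma,pfs1_tau True ln HR_PFS1 is
#'   `pfs1_gamma * ln HR_PFS2* + Normal(0, pfs1_tau^2)` — a noisier, typically
#'   larger-effect correlate of PFS2.
#' @param missing_rate Probability each optional field is deleted (missing
#'   completely at random, written as "NR" on disk).
#' @param seed Integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_trials = 15, beta0 = -0.05, beta1 = 0.53,
                             tau = 0.25, sigma = 0.13, mu_x = log(0.65),
                             n_range = c(112, 1050),
                             os_maturity_range = c(0.124, 0.595),
                             pfs2_maturity_range = c(0.27, 0.824),
                             info_fraction_range = c(0.24, 1.57),
                             os_maturity_longterm_range = c(0.45, 0.754),
                             longterm_fraction = 10 / 18,
                             crossover_range = c(0, 48),
                             crossover_attenuation = 0.5,
                             unbalanced_prob = 0.4,
                             pfs1_gamma = 1.2, pfs1_tau = 0.15,
                             missing_rate = 0.0, seed = 1L) {
  cfg <- list(
    n_trials = as.integer(n_trials), beta0 = beta0, beta1 = beta1,
    tau = tau, sigma = sigma, mu_x = mu_x, n_range = n_range,
    os_maturity_range = os_maturity_range,
    pfs2_maturity_range = pfs2_maturity_range,
    info_fraction_range = info_fraction_range,
    os_maturity_longterm_range = os_maturity_longterm_range,
    longterm_fraction = longterm_fraction,
    crossover_range = crossover_range,
    crossover_attenuation = crossover_attenuation,
    unbalanced_prob = unbalanced_prob,
    pfs1_gamma = pfs1_gamma, pfs1_tau = pfs1_tau,
    missing_rate = missing_rate, seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_trials >= 3, tau >= 0, sigma >= 0,
    missing_rate >= 0, missing_rate < 1,
    crossover_attenuation >= 0, crossover_attenuation <= 1
  )
  for (rg in list(n_range, os_maturity_range, pfs2_maturity_range,
                  info_fraction_range, os_maturity_longterm_range,
                  crossover_range)) {
    stopifnot(length(rg) == 2, rg[1] <= rg[2])
  }
  structure(cfg, class = "synthetic_config")
}

.runif_range <- function(n, range) stats::runif(n, range[1], range[2])

#' Generate a synthetic trial set with known ground truth
#'
#' Draws `n_trials` trials under the linear surrogacy model of the package
#' (see [synthetic_config()]). Per trial: the total N is uniform over
#' `n_range` split 1:1 (or 2:1 with probability `unbalanced_prob`); the true
#' ln HR_PFS2 is Normal(`mu_x`, `tau`^2); the true ln HR_OS follows the
#' surrogacy line plus Normal(0, `sigma`^2); maturities and the information
#' fraction are uniform over their ranges; observed event counts are
#' maturity x N (rounded); observed log HRs add independent
#' Normal(0, (2/sqrt(events))^2) estimation noise per endpoint, with 95% CIs
#' at estimate +/- 1.96 x 2/sqrt(events) exponentiated. The long-term OS
#' effect is the true effect shrunk toward zero by
#' `crossover_attenuation x crossover/100`, re-observed at long-term event
#' counts. PFS1 is a noisier correlate of PFS2 observed with the PFS2 noise
#' scale. Any draw yielding fewer than 5 events for an endpoint is redrawn
#' (and counted), keeping noise scales sane. Optional fields are then deleted
#' completely at random at `missing_rate`.
#'
#' Arm-level medians are generated for consistency with the hazard ratios
#' under a proportional-hazards exponential approximation (median ratio =
#' 1/HR), with control-arm median OS uniform on 20-40 months and a PFS2/OS
#' ratio uniform on 0.45-0.85.
#'
#' @param config A [synthetic_config()].
#' @return List with `trials` (a `trial_set`) and `truth` (data frame of
#'   latent per-trial values plus the generating parameters as attributes,
#'   including `n_redrawn`).
#' @export
generate_trials <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  local_seed(config$seed, {
    n <- config$n_trials
    rows <- vector("list", n)
    truth <- vector("list", n)
    n_redrawn <- 0L
    longterm_n <- round(config$longterm_fraction * n)
    longterm_idx <- if (longterm_n > 0) sample.int(n, longterm_n) else integer(0)
    for (i in seq_len(n)) {
      repeat {
        total <- round(.runif_range(1, config$n_range))
        unbalanced <- stats::runif(1) < config$unbalanced_prob
        n_int <- if (unbalanced) round(total * 2 / 3) else round(total / 2)
        n_ctrl <- total - n_int
        os_mat <- .runif_range(1, config$os_maturity_range)
        pfs2_mat <- .runif_range(1, config$pfs2_maturity_range)
        info <- .runif_range(1, config$info_fraction_range)
        os_events <- round(os_mat * total)
        pfs2_events <- round(pfs2_mat * total)
        lt <- i %in% longterm_idx
        os_mat_lt <- if (lt) .runif_range(1, config$os_maturity_longterm_range) else NA
        os_events_lt <- if (lt) round(os_mat_lt * total) else NA
        if (os_events >= 5 && pfs2_events >= 5 &&
            (!lt || os_events_lt >= 5)) break
        n_redrawn <- n_redrawn + 1L
      }
      x_true <- stats::rnorm(1, config$mu_x, config$tau)
      y_true <- config$beta0 + config$beta1 * x_true +
        stats::rnorm(1, 0, config$sigma)
      pfs1_true <- config$pfs1_gamma * x_true +
        stats::rnorm(1, 0, config$pfs1_tau)
      crossover <- .runif_range(1, config$crossover_range)
      se_os <- 2 / sqrt(os_events)
      se_pfs2 <- 2 / sqrt(pfs2_events)
      se_pfs1 <- se_pfs2
      obs <- function(mu, se) {
        est <- stats::rnorm(1, mu, se)
        c(exp(est), exp(est - 1.96 * se), exp(est + 1.96 * se))
      }
      hr_pfs2 <- obs(x_true, se_pfs2)
      hr_os <- obs(y_true, se_os)
      hr_pfs1 <- obs(pfs1_true, se_pfs1)
      lt <- i %in% longterm_idx
      if (lt) {
        shrink <- 1 - config$crossover_attenuation * crossover / 100
        y_lt_true <- y_true * shrink
        se_lt <- 2 / sqrt(os_events_lt)
        hr_os_lt <- obs(y_lt_true, se_lt)
      } else {
        y_lt_true <- NA
        hr_os_lt <- c(NA, NA, NA)
      }
      med_os_ctrl <- stats::runif(1, 20, 40)
      med_os_int <- med_os_ctrl / exp(y_true)
      ratio <- stats::runif(1, 0.45, 0.85)
      med_pfs2_ctrl <- ratio * med_os_ctrl
      med_pfs2_int <- ratio * med_os_int
      rows[[i]] <- data.frame(
        trial_id = sprintf("SYN-%03d", i),
        year = 2014 + (i %% 12),
        subtype = sample(.subtype_levels, 1, prob = c(11, 4, 3)),
        prior_lines = sample(c("0", "1", ">1"), 1),
        pfs2_in_protocol = sample(c("yes", "no"), 1),
        pfs2_designation = sample(.designation_levels, 1,
                                  prob = c(2, 5, 10)),
        pfs2_line = NA_character_,
        n_intervention = n_int, n_control = n_ctrl,
        hr_pfs1 = hr_pfs1[1], hr_pfs1_low = hr_pfs1[2], hr_pfs1_high = hr_pfs1[3],
        hr_pfs2 = hr_pfs2[1], hr_pfs2_low = hr_pfs2[2], hr_pfs2_high = hr_pfs2[3],
        hr_os_initial = hr_os[1], hr_os_initial_low = hr_os[2],
        hr_os_initial_high = hr_os[3],
        hr_os_longterm = hr_os_lt[1], hr_os_longterm_low = hr_os_lt[2],
        hr_os_longterm_high = hr_os_lt[3],
        median_pfs2_int = med_pfs2_int, median_pfs2_ctrl = med_pfs2_ctrl,
        median_os_int = med_os_int, median_os_ctrl = med_os_ctrl,
        os_events = os_events, os_denominator = total,
        os_planned_events = round(os_events / info),
        pfs2_events = pfs2_events, pfs2_denominator = total,
        os_events_longterm = os_events_lt,
        os_denominator_longterm = if (lt) total else NA,
        crossover_pct = if (lt) crossover else NA,
        longterm_available = lt,
        stringsAsFactors = FALSE
      )
      rows[[i]]$pfs2_line <-
        if (rows[[i]]$prior_lines == "0") "second_line" else "later_line"
      truth[[i]] <- data.frame(
        trial_id = rows[[i]]$trial_id,
        x_true = x_true, y_true = y_true, y_longterm_true = y_lt_true,
        pfs1_true = pfs1_true,
        se_pfs2 = se_pfs2, se_os = se_os,
        crossover_pct = crossover,
        stringsAsFactors = FALSE
      )
    }
    df <- do.call(rbind, rows)
    if (config$missing_rate > 0) {
      # HR triplets are deleted jointly (a CI is never reported without its
      # point estimate), driven by the point column's missingness draw
      optional <- setdiff(
        trial_columns(),
        c("trial_id", "year", "subtype", "n_intervention", "n_control",
          "longterm_available", paste0("hr_", .hr_endpoints, "_low"),
          paste0("hr_", .hr_endpoints, "_high"))
      )
      for (col in optional) {
        hit <- stats::runif(nrow(df)) < config$missing_rate
        df[[col]][hit] <- NA
      }
      for (ep in .hr_endpoints) {
        pt <- paste0("hr_", ep)
        miss <- is.na(df[[pt]])
        df[[paste0(pt, "_low")]][miss] <- NA
        df[[paste0(pt, "_high")]][miss] <- NA
      }
    }
    truth_df <- do.call(rbind, truth)
    attr(truth_df, "config") <- config
    attr(truth_df, "n_redrawn") <- n_redrawn
    list(
      trials = as_trial_set(df, provenance = sprintf(
        "synthetic:seed=%d", config$seed
      )),
      truth = truth_df
    )
  })
}

#' Paper-like synthetic fixture
#'
#' An 18-trial synthetic set shaped like the study-characteristics table of
#' the breast-cancer PFS2 literature: 18 trials of which exactly 15 carry
#' complete (PFS2, OS) hazard ratios (3 have PFS2 HRs structurally missing,
#' as happens when results exist only in congress abstracts), 10 carry
#' long-term OS follow-up, information fractions span values above 100%, and
#' maturities cover the observed ranges. Intended for end-to-end demos and
#' pipeline tests; it is synthetic, not extracted data.
#'
#' @param seed Integer seed.
#' @return A `trial_set` of 18 records.
#' @export
paperlike_fixture <- function(seed = 1L) {
  cfg <- synthetic_config(n_trials = 18, longterm_fraction = 10 / 18,
                          missing_rate = 0, seed = seed)
  gen <- generate_trials(cfg)
  df <- as.data.frame(gen$trials)
  drop_idx <- local_seed(derive_seed(seed, 7919), sample.int(18, 3))
  for (col in c("hr_pfs2", "hr_pfs2_low", "hr_pfs2_high",
                "median_pfs2_int", "median_pfs2_ctrl")) {
    df[[col]][drop_idx] <- NA
  }
  # guarantee at least one information fraction above 100%
  info <- df$os_events / df$os_planned_events
  if (all(info <= 1, na.rm = TRUE)) {
    k <- which.max(info)
    df$os_planned_events[k] <- max(1, round(df$os_events[k] / 1.12))
  }
  as_trial_set(df, provenance = sprintf("synthetic:paperlike:seed=%d", seed))
}
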