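# Secondary analyses: long-term OS validation, OS-effect drift versus the
# PFS2 effect, arm-level median PFS2/OS correlation and ratio summaries, and
# subtype-restricted surrogacy.

#' Spearman rank correlation with small-sample exact p
#'
#' Rank-based correlation with average ranks for ties. The two-sided p-value
#' is the exact permutation p when n <= 9 (feasible and preferable at the
#' tiny subgroup sizes trial-level analyses produce) and the large-sample
#' approximation otherwise; with ties the approximation is always used.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho` and `p`.
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (anyNA(x) || anyNA(y)) stop("missing values in input")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("degenerate input: constant sequence")
  }
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  use_exact <- n <= 9 && !has_ties
  ct <- suppressWarnings(stats::cor.test(
    x, y, method = "spearman", exact = use_exact, alternative = "two.sided"
  ))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Arm-level median observations
#'
#' Reshapes a trial set to one row per treatment arm with both median PFS2
#' and median OS (months) reported. The per-arm ratio median PFS2 / median OS
#' is attached; ratios above 1 (PFS2 exceeding OS, ordinarily impossible and
#' a sign of extraction issues) are kept but flagged.
#'
#' @param trials A `trial_set`.
#' @return Data frame with `trial_id`, `arm` (`"intervention"`/`"control"`),
#'   `median_pfs2`, `median_os`, `ratio`, `ratio_above_1`.
#' @export
arm_observations <- function(trials) {
  mk <- function(arm, pfs2_col, os_col) {
    data.frame(
      trial_id = trials$trial_id, arm = arm,
      median_pfs2 = as.numeric(trials[[pfs2_col]]),
      median_os = as.numeric(trials[[os_col]]),
      stringsAsFactors = FALSE
    )
  }
  obs <- rbind(
    mk("intervention", "median_pfs2_int", "median_os_int"),
    mk("control", "median_pfs2_ctrl", "median_os_ctrl")
  )
  obs <- obs[!is.na(obs$median_pfs2) & !is.na(obs$median_os), , drop = FALSE]
  if (nrow(obs) > 0 && any(obs$median_pfs2 <= 0 | obs$median_os <= 0)) {
    stop("medians must be positive")
  }
  obs$ratio <- obs$median_pfs2 / obs$median_os
  obs$ratio_above_1 <- obs$ratio > 1
  if (any(obs$ratio_above_1)) {
    warning("arm(s) with median PFS2 exceeding median OS: ",
            paste(obs$trial_id[obs$ratio_above_1], collapse = ", "))
  }
  rownames(obs) <- NULL
  obs
}

#' Arm-level Spearman correlation of median PFS2 and median OS
#'
#' Pools all arms with both medians available and correlates median PFS2 with
#' median OS across arms.
#'
#' @param trials A `trial_set`.
#' @return List with `rho`, `p`, `n_arms`, `observations`.
#' @export
arm_median_correlation <- function(trials) {
  obs <- arm_observations(trials)
  if (nrow(obs) < 3) stop("insufficient arms: need >= 3, got ", nrow(obs))
  s <- spearman_rho(obs$median_pfs2, obs$median_os)
  list(rho = s$rho, p = s$p, n_arms = nrow(obs), observations = obs)
}

#' Median PFS2/OS ratio summary per arm
#'
#' Summarizes the distribution of per-trial ratios median PFS2 / median OS
#' within one arm: the central value is the across-trial median of the
#' per-trial ratios (mean of the middle two for an even count), with the
#' observed range, plus the count of trials whose median PFS2 fell in the
#' earlier half of the OS timeline (ratio strictly below 0.50; ties at
#' exactly 0.50 do not count).
#'
#' @param arms Arm-level data frame from [arm_observations()].
#' @param arm `"intervention"` or `"control"`.
#' @return List with `central`, `min`, `max`, `n`, `n_below_half`.
#' @export
median_ratio_summary <- function(arms, arm = c("intervention", "control")) {
  arm <- match.arg(arm)
  sub <- arms[arms$arm == arm, , drop = FALSE]
  if (nrow(sub) < 1) stop("no observations for arm: ", arm)
  list(
    central = stats::median(sub$ratio),
    min = min(sub$ratio),
    max = max(sub$ratio),
    n = nrow(sub),
    n_below_half = sum(sub$ratio < 0.50)
  )
}

#' Long-term OS validation analysis
#'
#' Reruns the trial-level surrogacy analysis with the long-term follow-up OS
#' hazard ratio as the true endpoint, restricted to trials that reported
#' updated OS data. Identical contracts to [run_surrogacy()].
#'
#' @inheritParams run_surrogacy
#' @return A `surrogacy_result`.
#' @export
validation_longterm <- function(trials, x_endpoint = "pfs2",
                                weighting = "total_n", n_boot = 2000,
                                seed = 1L, level = 0.95, quiet = FALSE) {
  run_surrogacy(
    trials, x_endpoint = x_endpoint, y_endpoint = "os_longterm",
    weighting = weighting, n_boot = n_boot, seed = seed, level = level,
    quiet = quiet
  )
}

#' OS-effect drift versus the PFS2 effect
#'
#' For trials reporting OS at both the initial and a long-term data cut,
#' computes the drift Delta log(HR OS) = ln(HR OS long-term) - ln(HR OS
#' initial) and its Spearman correlation with ln(HR PFS2). A negative rho
#' indicates that trials with larger PFS2 benefit saw their OS effect
#' attenuate (HR move toward or past 1) with longer follow-up.
#'
#' @param trials A `trial_set`.
#' @param quiet Suppress exclusion messages.
#' @return List with `rho`, `p`, `n`, `observations` (trial_id,
#'   `log_hr_pfs2`, `delta_log_hr_os`). If every long-term HR equals its
#'   initial HR the drift is identically zero and a "no drift" error is
#'   raised (the correlation is undefined).
#' @export
drift_analysis <- function(trials, quiet = FALSE) {
  sub <- analysis_subset(
    trials, c("hr_pfs2", "hr_os_initial", "hr_os_longterm"),
    min_n = 3, quiet = quiet
  )
  obs <- data.frame(
    trial_id = sub$trial_id,
    log_hr_pfs2 = log(as.numeric(sub$hr_pfs2)),
    delta_log_hr_os = log(as.numeric(sub$hr_os_longterm)) -
      log(as.numeric(sub$hr_os_initial)),
    stringsAsFactors = FALSE
  )
  if (all(obs$delta_log_hr_os == 0)) {
    stop("no drift: every long-term HR equals its initial HR; ",
         "correlation undefined")
  }
  s <- tryCatch(
    spearman_rho(obs$log_hr_pfs2, obs$delta_log_hr_os),
    error = function(e) stop("degenerate drift inputs: ", conditionMessage(e))
  )
  list(rho = s$rho, p = s$p, n = nrow(obs), observations = obs)
}

#' Subtype-restricted surrogacy analysis
#'
#' Runs the surrogacy analysis within one breast-cancer subtype. Initial OS
#' is the default true endpoint. Results at n = 3 carry an
#' "insufficient precision" warning: bootstrap CIs at that size routinely
#' span [-1, 1].
#'
#' @param trials A `trial_set`.
#' @param subtype One of `"HRpos_HER2neg"`, `"HER2pos"`, `"HER2neg_mixed"`.
#' @inheritParams run_surrogacy
#' @return A `surrogacy_result`.
#' @export
subtype_subset_analysis <- function(trials, subtype,
                                    x_endpoint = "pfs2",
                                    y_endpoint = "os_initial",
                                    weighting = "total_n", n_boot = 2000,
                                    seed = 1L, level = 0.95, quiet = FALSE) {
  subtype <- match.arg(subtype, .subtype_levels)
  sub <- trials[!is.na(trials$subtype) & trials$subtype == subtype, ,
                drop = FALSE]
  attr(sub, "provenance") <- attr(trials, "provenance")
  res <- run_surrogacy(
    sub, x_endpoint = x_endpoint, y_endpoint = y_endpoint,
    weighting = weighting, n_boot = n_boot, seed = seed, level = level,
    quiet = quiet
  )
  if (res$n == 3) {
    warning("subtype analysis on only 3 trials: insufficient precision")
  }
  res
}
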