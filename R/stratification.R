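# Maturity / information-fraction arithmetic and threshold subgroup analyses.
#
# Maturity = observed events / intention-to-treat patients at the time of
# analysis. Information fraction = observed events / protocol-planned events
# for the final analysis; it legitimately exceeds 1 when an analysis occurs
# after the planned event count has been surpassed, and is never clamped.

#' Event maturity or information fraction
#'
#' Exact quotient of events over a denominator (patients for maturity,
#' planned events for the information fraction). Values above 1 are valid for
#' information fractions. Rendering as a percentage is the reporting layer's
#' job ([format_percent()]).
#'
#' @param events Non-negative event count (vectorized).
#' @param denominator Positive denominator (vectorized).
#' @return Numeric quotient(s).
#' @examples
#' compute_maturity(39, 315)   # 0.1238... -> prints as 12.4%
#' compute_maturity(171, 152)  # 1.125     -> information fraction 112%
#' @export
compute_maturity <- function(events, denominator) {
  bad_den <- !is.na(denominator) & denominator < 1
  if (any(bad_den)) stop("denominator must be >= 1")
  bad_ev <- !is.na(events) & events < 0
  if (any(bad_ev)) stop("events must be >= 0")
  ifelse(is.na(events) | is.na(denominator), NA_real_, events / denominator)
}

#' Attach maturity metrics to a trial set
#'
#' Adds `os_maturity`, `os_information_fraction`, `pfs2_maturity` and
#' `os_maturity_longterm` columns, each the exact events/denominator quotient
#' and NA whenever either operand is missing.
#'
#' @param trials A `trial_set`.
#' @return The trial set with four additional numeric columns.
#' @export
add_maturity_metrics <- function(trials) {
  trials$os_maturity <-
    compute_maturity(trials$os_events, trials$os_denominator)
  trials$os_information_fraction <-
    compute_maturity(trials$os_events, trials$os_planned_events)
  trials$pfs2_maturity <-
    compute_maturity(trials$pfs2_events, trials$pfs2_denominator)
  trials$os_maturity_longterm <-
    compute_maturity(trials$os_events_longterm, trials$os_denominator_longterm)
  trials
}

.stratum_criteria <- c("pfs2_maturity", "os_information_fraction",
                       "os_maturity", "treatment_line", "crossover_exposure")

# Returns, per eligible trial, a stratum label (NA = criterion value missing,
# "" = value present but outside every defined stratum, e.g. OS maturity
# above 60% or crossover above 50%).
.assign_strata <- function(trials, criterion, cutpoints) {
  tm <- add_maturity_metrics(trials)
  pct <- function(p) format_percent(p)
  if (criterion == "pfs2_maturity" || criterion == "os_information_fraction") {
    cut <- cutpoints[1]
    v <- tm[[criterion]]
    lab <- ifelse(is.na(v), NA_character_,
                  ifelse(v >= cut, paste0(">=", pct(cut), "%"),
                         paste0("<", pct(cut), "%")))
  } else if (criterion == "os_maturity") {
    lo <- cutpoints[1]; hi <- cutpoints[2]
    v <- tm$os_maturity
    lab <- ifelse(is.na(v), NA_character_,
                  ifelse(v < lo, paste0("<", pct(lo), "%"),
                         ifelse(v <= hi, paste0(pct(lo), "-", pct(hi), "%"), "")))
  } else if (criterion == "crossover_exposure") {
    lo <- cutpoints[1]; hi <- cutpoints[2]
    v <- tm$crossover_pct / 100
    lab <- ifelse(is.na(v), NA_character_,
                  ifelse(v <= lo, paste0("0-", pct(lo), "%"),
                         ifelse(v <= hi, paste0(pct(lo), "-", pct(hi), "%"), "")))
  } else if (criterion == "treatment_line") {
    lab <- as.character(tm$pfs2_line)
  } else {
    stop("unsupported criterion: ", criterion)
  }
  lab
}

#' Threshold-stratified surrogacy analyses
#'
#' Splits eligible trials on a trial-level design/maturity criterion and runs
#' the full surrogacy analysis within each stratum. Supported criteria and
#' default cutpoints: `pfs2_maturity` at 0.55 (<55% vs >=55%),
#' `os_information_fraction` at 0.75, `os_maturity` at (0.40, 0.60) giving
#' strata <40% and 40-60% (trials above 60% are left unassigned and logged),
#' `crossover_exposure` at (0.30, 0.50) giving strata 0-30% (closed at 30%)
#' and 30-50%, and `treatment_line` (whether PFS2 reflects progression on
#' second-line versus later-line therapy). Boundary values land in the
#' closed-upper (">=") stratum. Trials missing the criterion value are
#' excluded and logged.
#'
#' Strata with fewer than 3 analyzable trials are returned with
#' `result = NULL` and `reason = "insufficient trials"` rather than a
#' fabricated fit.
#'
#' @param trials A `trial_set`.
#' @param criterion One of `"pfs2_maturity"`, `"os_information_fraction"`,
#'   `"os_maturity"`, `"treatment_line"`, `"crossover_exposure"`.
#' @param cutpoints Ordered numeric cutpoints on the proportion scale;
#'   defaults as above.
#' @param x_endpoint,y_endpoint,weighting,n_boot,seed,level,quiet Passed to
#'   [run_surrogacy()]; per-stratum bootstrap seeds are derived as
#'   `seed + stratum index` for reproducibility.
#' @return List of class `stratified_result`; elements carry `criterion`,
#'   `stratum`, `trial_ids`, and `result` (a `surrogacy_result` or NULL with
#'   a `reason`). Attributes record unassigned and excluded-missing trials.
#' @export
stratify <- function(trials, criterion, cutpoints = NULL,
                     x_endpoint = "pfs2", y_endpoint = "os_initial",
                     weighting = "total_n", n_boot = 2000, seed = 1L,
                     level = 0.95, quiet = FALSE) {
  criterion <- match.arg(criterion, .stratum_criteria)
  if (is.null(cutpoints)) {
    cutpoints <- switch(criterion,
      pfs2_maturity = 0.55,
      os_information_fraction = 0.75,
      os_maturity = c(0.40, 0.60),
      crossover_exposure = c(0.30, 0.50),
      treatment_line = numeric(0)
    )
  }
  if (is.unsorted(cutpoints)) stop("cutpoints must be ordered")
  # restrict to trials analyzable for the endpoint pair first
  xcol <- .endpoint_column(x_endpoint)
  ycol <- .endpoint_column(y_endpoint)
  elig <- analysis_subset(trials, unique(c(xcol, ycol)), quiet = quiet)
  lab <- .assign_strata(elig, criterion, cutpoints)
  missing_ids <- elig$trial_id[is.na(lab)]
  unassigned_ids <- elig$trial_id[!is.na(lab) & lab == ""]
  if (!quiet && length(missing_ids) > 0) {
    message("excluded (missing ", criterion, "): ",
            paste(missing_ids, collapse = ", "))
  }
  if (!quiet && length(unassigned_ids) > 0) {
    message("unassigned (outside defined strata for ", criterion, "): ",
            paste(unassigned_ids, collapse = ", "))
  }
  levels_order <- unique(lab[!is.na(lab) & lab != ""])
  levels_order <- sort(levels_order)
  out <- vector("list", length(levels_order))
  for (k in seq_along(levels_order)) {
    in_stratum <- !is.na(lab) & lab == levels_order[k]
    sub <- elig[in_stratum, , drop = FALSE]
    entry <- list(
      criterion = criterion, stratum = levels_order[k],
      trial_ids = sub$trial_id, n = nrow(sub), result = NULL, reason = NULL
    )
    if (nrow(sub) < 3) {
      entry$reason <- "insufficient trials"
    } else {
      entry$result <- run_surrogacy(
        sub, x_endpoint = x_endpoint, y_endpoint = y_endpoint,
        weighting = weighting, n_boot = n_boot,
        seed = derive_seed(seed, k), level = level, quiet = TRUE
      )
    }
    out[[k]] <- entry
  }
  structure(
    out,
    class = "stratified_result",
    criterion = criterion, cutpoints = cutpoints,
    excluded_missing = missing_ids, unassigned = unassigned_ids
  )
}

#' Tabulate a stratified analysis
#'
#' @param strat A `stratified_result` from [stratify()].
#' @return Data frame with one row per stratum: criterion, stratum, n, r, CI,
#'   R2, slope, p (NA rows for strata with insufficient trials).
#' @export
stratified_table <- function(strat) {
  stopifnot(inherits(strat, "stratified_result"))
  rows <- lapply(strat, function(e) {
    if (is.null(e$result)) {
      data.frame(
        criterion = e$criterion, stratum = e$stratum, n = e$n,
        r = NA_real_, r_ci_low = NA_real_, r_ci_high = NA_real_,
        r2 = NA_real_, slope = NA_real_, slope_p = NA_real_,
        note = e$reason, stringsAsFactors = FALSE
      )
    } else {
      s <- e$result
      data.frame(
        criterion = e$criterion, stratum = e$stratum, n = e$n,
        r = s$r, r_ci_low = s$r_ci_low, r_ci_high = s$r_ci_high,
        r2 = s$r2, slope = s$fit$slope, slope_p = s$fit$slope_p,
        note = "", stringsAsFactors = FALSE
      )
    }
  })
  do.call(rbind, rows)
}

#' @export
print.stratified_result <- function(x, ...) {
  cat("Stratified surrogacy analysis by", attr(x, "criterion"), "\n")
  print(stratified_table(x), ...)
  invisible(x)
}
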