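# Full analysis pipeline and report rendering.

#' Analysis configuration
#'
#' Bundles the tunable settings of the full pipeline: bootstrap size and CI
#' level, weighting scheme, and the stratification thresholds (PFS2 maturity
#' 0.55, OS information fraction 0.75, OS maturity 0.40/0.60, crossover
#' 0.30/0.50 — all on the proportion scale).
#'
#' @param seed Integer seed governing every bootstrap in the run.
#' @param n_boot Bootstrap replicates (>= 200).
#' @param ci_level CI level in (0, 1).
#' @param weighting `"total_n"` or `"equal"`.
#' @param pfs2_maturity_cut,os_info_fraction_cut Single cutpoints.
#' @param os_maturity_cuts,crossover_cuts Length-2 cutpoints.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(seed = 1L, n_boot = 2000, ci_level = 0.95,
                            weighting = "total_n",
                            pfs2_maturity_cut = 0.55,
                            os_info_fraction_cut = 0.75,
                            os_maturity_cuts = c(0.40, 0.60),
                            crossover_cuts = c(0.30, 0.50)) {
  stopifnot(ci_level > 0, ci_level < 1, n_boot >= 200,
            pfs2_maturity_cut > 0, os_info_fraction_cut > 0,
            length(os_maturity_cuts) == 2, length(crossover_cuts) == 2)
  structure(
    list(
      seed = as.integer(seed), n_boot = as.integer(n_boot),
      ci_level = ci_level, weighting = weighting,
      pfs2_maturity_cut = pfs2_maturity_cut,
      os_info_fraction_cut = os_info_fraction_cut,
      os_maturity_cuts = os_maturity_cuts,
      crossover_cuts = crossover_cuts
    ),
    class = "analysis_config"
  )
}

.section <- function(fun) {
  tryCatch(
    list(status = "ok", value = suppressMessages(suppressWarnings(fun()))),
    error = function(e) list(status = "skipped",
                             reason = conditionMessage(e), value = NULL)
  )
}

#' Run the complete surrogacy analysis sequence
#'
#' Executes, each on its own eligibility subset: (1) the primary PFS2-OS
#' analysis, (2) long-term OS validation, (3-7) subgroup analyses by PFS2
#' maturity, OS information fraction, OS maturity, treatment line and
#' control-arm crossover exposure, (8) the OS-drift Spearman analysis,
#' (9) arm-level median correlation and ratio summaries, (10) leave-one-out
#' sensitivity, (11) subtype-restricted analyses, and (12) the PFS1-OS
#' comparison with its long-term validation. Analyses whose preconditions
#' fail (too few trials, missing fields) are reported as skipped with the
#' reason, never silently omitted. The whole report is a pure function of the
#' input table and the configuration; rerunning with the same seed reproduces
#' it exactly.
#'
#' @param trials A `trial_set`.
#' @param config An [analysis_config()].
#' @return Object of class `surrogacy_report`: named list of sections, each
#'   `list(status, value | reason)`, plus the config and provenance.
#' @export
run_full_analysis <- function(trials, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  s <- config$seed; nb <- config$n_boot; lv <- config$ci_level
  wt <- config$weighting
  strat_call <- function(criterion, cuts, y = "os_initial", seed_off) {
    function() stratify(
      trials, criterion, cutpoints = cuts, y_endpoint = y, weighting = wt,
      n_boot = nb, seed = derive_seed(s, seed_off), level = lv, quiet = TRUE
    )
  }
  sections <- list(
    primary = .section(function() run_surrogacy(
      trials, "pfs2", "os_initial", weighting = wt, n_boot = nb,
      seed = s, level = lv, quiet = TRUE
    )),
    validation_longterm = .section(function() validation_longterm(
      trials, weighting = wt, n_boot = nb, seed = derive_seed(s, 1),
      level = lv, quiet = TRUE
    )),
    pfs2_maturity = .section(
      strat_call("pfs2_maturity", config$pfs2_maturity_cut, seed_off = 100)
    ),
    os_information_fraction = .section(
      strat_call("os_information_fraction", config$os_info_fraction_cut,
                 seed_off = 200)
    ),
    os_maturity = .section(
      strat_call("os_maturity", config$os_maturity_cuts, seed_off = 300)
    ),
    treatment_line = .section(
      strat_call("treatment_line", numeric(0), seed_off = 400)
    ),
    crossover_exposure = .section(
      strat_call("crossover_exposure", config$crossover_cuts,
                 y = "os_longterm", seed_off = 500)
    ),
    drift = .section(function() drift_analysis(trials, quiet = TRUE)),
    arm_medians = .section(function() {
      corr <- arm_median_correlation(trials)
      list(
        correlation = corr,
        intervention = median_ratio_summary(corr$observations, "intervention"),
        control = median_ratio_summary(corr$observations, "control")
      )
    }),
    leave_one_out = .section(function() leave_one_out(
      trials, weighting = wt, n_boot = nb, seed = derive_seed(s, 600),
      level = lv, quiet = TRUE
    )),
    subtypes = .section(function() {
      out <- list()
      for (st in .subtype_levels) {
        out[[st]] <- .section(function() subtype_subset_analysis(
          trials, st, weighting = wt, n_boot = nb,
          seed = derive_seed(s, 700 + stable_hash(st) %% 100),
          level = lv, quiet = TRUE
        ))
      }
      out
    }),
    pfs1 = .section(function() run_surrogacy(
      trials, "pfs1", "os_initial", weighting = wt, n_boot = nb,
      seed = derive_seed(s, 800), level = lv, quiet = TRUE
    )),
    pfs1_longterm = .section(function() run_surrogacy(
      trials, "pfs1", "os_longterm", weighting = wt, n_boot = nb,
      seed = derive_seed(s, 900), level = lv, quiet = TRUE
    ))
  )
  structure(
    list(
      sections = sections, config = config,
      provenance = attr(trials, "provenance") %||% "unknown",
      n_input = nrow(trials)
    ),
    class = "surrogacy_report"
  )
}

.jsonify_section <- function(sec) {
  if (sec$status != "ok") return(list(status = sec$status, reason = sec$reason))
  v <- sec$value
  body <-
    if (inherits(v, "surrogacy_result")) {
      list(
        n = v$n, r = v$r, r_ci_low = v$r_ci_low, r_ci_high = v$r_ci_high,
        r2 = v$r2, slope = v$fit$slope, intercept = v$fit$intercept,
        slope_se = v$fit$slope_se, slope_p = v$fit$slope_p,
        strength = v$strength, iqwig = v$iqwig, negative_r = v$negative_r,
        weights = v$weights, n_boot = v$n_boot, seed = v$seed,
        trial_ids = v$trial_ids
      )
    } else if (inherits(v, "stratified_result")) {
      list(
        criterion = attr(v, "criterion"),
        excluded_missing = attr(v, "excluded_missing"),
        unassigned = attr(v, "unassigned"),
        strata = lapply(v, function(e) {
          base <- list(stratum = e$stratum, n = e$n, trial_ids = e$trial_ids)
          if (is.null(e$result)) c(base, list(note = e$reason))
          else c(base, .jsonify_section(list(status = "ok", value = e$result)))
        })
      )
    } else if (inherits(v, "loo_report")) {
      list(
        iterations = v$table,
        r_min = v$r_min, r_max = v$r_max, r2_min = v$r2_min,
        r2_max = v$r2_max, slope_min = v$slope_min, slope_max = v$slope_max,
        p_min = v$p_min, p_max = v$p_max,
        all_positive = v$all_positive, all_significant = v$all_significant
      )
    } else if (is.list(v) && !is.null(v$rho)) {
      list(rho = v$rho, p = v$p, n = v$n %||% v$n_arms,
           observations = v$observations)
    } else if (is.list(v)) {
      lapply(v, function(el) {
        if (is.list(el) && !is.null(el$status)) .jsonify_section(el)
        else el
      })
    } else v
  c(list(status = "ok"), body)
}

#' Render a report as JSON or aligned text
#'
#' The JSON rendering carries every computed number at full precision; the
#' text rendering rounds r and R2 to 3 decimals and slopes/p to 3 significant
#' figures. Both are deterministic given the input and seed.
#'
#' @param report A `surrogacy_report`.
#' @param format `"json"` or `"text"`.
#' @param path Optional output file; when NULL the rendering is returned.
#' @return Character scalar (invisibly when written to `path`).
#' @export
render_report <- function(report, format = c("json", "text"), path = NULL) {
  stopifnot(inherits(report, "surrogacy_report"))
  format <- match.arg(format)
  out <- if (format == "json") {
    payload <- list(
      provenance = report$provenance,
      n_input_trials = report$n_input,
      config = unclass(report$config),
      sections = lapply(report$sections, .jsonify_section)
    )
    as.character(jsonlite::toJSON(
      payload, auto_unbox = TRUE, digits = NA, null = "null", na = "null",
      dataframe = "rows", pretty = TRUE
    ))
  } else {
    paste(utils::capture.output(print(report)), collapse = "\n")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' @export
print.surrogacy_report <- function(x, digits = 3, ...) {
  cat("=== Trial-level surrogacy report ===\n")
  cat("input:", x$provenance, "|", x$n_input, "trials | seed",
      x$config$seed, "| n_boot", x$config$n_boot, "\n")
  fmt_sr <- function(v) {
    sprintf(
      "n=%d  r=%s (%s to %s)  R2=%s  slope=%s  p=%s  [%s/%s]",
      v$n, round(v$r, digits), round(v$r_ci_low, digits),
      round(v$r_ci_high, digits), round(v$r2, digits),
      signif(v$fit$slope, digits), signif(v$fit$slope_p, digits),
      v$strength, v$iqwig
    )
  }
  for (name in names(x$sections)) {
    sec <- x$sections[[name]]
    cat("\n--", name, "--\n")
    if (sec$status != "ok") {
      cat("skipped:", sec$reason, "\n")
      next
    }
    v <- sec$value
    if (inherits(v, "surrogacy_result")) {
      cat(fmt_sr(v), "\n")
    } else if (inherits(v, "stratified_result")) {
      tab <- stratified_table(v)
      num <- vapply(tab, is.numeric, logical(1))
      tab[num] <- lapply(tab[num], function(c) signif(c, digits))
      print(tab, row.names = FALSE)
    } else if (inherits(v, "loo_report")) {
      cat(sprintf(
        "r in [%s, %s]; R2 in [%s, %s]; slope in [%s, %s]; p in [%s, %s]; all positive: %s; all p<%s: %s\n",
        round(v$r_min, digits), round(v$r_max, digits),
        round(v$r2_min, digits), round(v$r2_max, digits),
        signif(v$slope_min, digits), signif(v$slope_max, digits),
        signif(v$p_min, digits), signif(v$p_max, digits),
        v$all_positive, v$p_threshold, v$all_significant
      ))
    } else if (name == "drift") {
      cat(sprintf("n=%d  Spearman rho=%s  p=%s\n",
                  v$n, round(v$rho, digits), signif(v$p, digits)))
    } else if (name == "arm_medians") {
      cat(sprintf("arms=%d  Spearman rho=%s  p=%s\n",
                  v$correlation$n_arms, round(v$correlation$rho, digits),
                  signif(v$correlation$p, digits)))
      for (arm in c("intervention", "control")) {
        m <- v[[arm]]
        cat(sprintf(
          "  %s: median ratio %s (range %s-%s), %d/%d trials with ratio < 0.50\n",
          arm, round(m$central, 2), round(m$min, 2), round(m$max, 2),
          m$n_below_half, m$n
        ))
      }
    } else if (name == "subtypes") {
      for (st in names(v)) {
        sec2 <- v[[st]]
        if (sec2$status == "ok") cat(st, ": ", fmt_sr(sec2$value), "\n", sep = "")
        else cat(st, ": skipped: ", sec2$reason, "\n", sep = "")
      }
    }
  }
  invisible(x)
}
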