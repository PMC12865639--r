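# Leave-one-out sensitivity analysis of the primary surrogacy regression.

#' Leave-one-out sensitivity analysis
#'
#' Repeats the trial-level surrogacy analysis with each analyzable trial
#' excluded in turn and summarizes the spread of r, R2, slope and slope p
#' across iterations, plus two robustness flags: whether every iteration kept
#' a positive correlation and whether every slope stayed significant at the
#' two-sided 0.05 level. Bootstrap CIs are computed within each iteration
#' (they are part of each `surrogacy_result`) but the headline table reports
#' point estimates and p-values. Per-iteration seeds derive from the base
#' seed plus a stable hash of the left-out trial id, so results are
#' independent of iteration order.
#'
#' @inheritParams run_surrogacy
#' @param p_threshold Significance threshold for `all_significant`
#'   (default 0.05).
#' @return Object of class `loo_report`: `iterations` (named list of
#'   `surrogacy_result`s keyed by left-out trial id), `table` (one row per
#'   iteration), extrema (`r_min`, `r_max`, `r2_min`, `r2_max`, `slope_min`,
#'   `slope_max`, `p_min`, `p_max`), `all_positive`, `all_significant`.
#' @export
leave_one_out <- function(trials, x_endpoint = "pfs2",
                          y_endpoint = "os_initial", weighting = "total_n",
                          n_boot = 2000, seed = 1L, level = 0.95,
                          p_threshold = 0.05, quiet = FALSE) {
  xcol <- .endpoint_column(x_endpoint)
  ycol <- .endpoint_column(y_endpoint)
  base <- analysis_subset(trials, unique(c(xcol, ycol)), quiet = quiet)
  if (nrow(base) < 4) {
    stop("insufficient trials: leave-one-out needs >= 4 analyzable, got ",
         nrow(base))
  }
  ids <- sort(base$trial_id)
  iterations <- setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    rest <- base[base$trial_id != id, , drop = FALSE]
    attr(rest, "provenance") <- attr(trials, "provenance")
    iterations[[id]] <- run_surrogacy(
      rest, x_endpoint = x_endpoint, y_endpoint = y_endpoint,
      weighting = weighting, n_boot = n_boot,
      seed = derive_seed(seed, stable_hash(id)), level = level, quiet = TRUE
    )
  }
  tab <- do.call(rbind, lapply(ids, function(id) {
    s <- iterations[[id]]
    data.frame(
      left_out = id, n = s$n, r = s$r, r2 = s$r2, slope = s$fit$slope,
      slope_p = s$fit$slope_p, stringsAsFactors = FALSE
    )
  }))
  structure(
    list(
      iterations = iterations, table = tab,
      r_min = min(tab$r), r_max = max(tab$r),
      r2_min = min(tab$r2), r2_max = max(tab$r2),
      slope_min = min(tab$slope), slope_max = max(tab$slope),
      p_min = min(tab$slope_p), p_max = max(tab$slope_p),
      all_positive = all(tab$r > 0),
      all_significant = all(tab$slope_p < p_threshold),
      p_threshold = p_threshold, seed = as.integer(seed)
    ),
    class = "loo_report"
  )
}

#' @export
print.loo_report <- function(x, digits = 3, ...) {
  cat(sprintf("Leave-one-out sensitivity analysis (%d iterations)\n",
              nrow(x$table)))
  tab <- x$table
  tab$r <- round(tab$r, digits); tab$r2 <- round(tab$r2, digits)
  tab$slope <- signif(tab$slope, digits)
  tab$slope_p <- signif(tab$slope_p, digits)
  print(tab, row.names = FALSE, ...)
  cat(sprintf(
    "r in [%s, %s]; R2 in [%s, %s]; slope in [%s, %s]; p in [%s, %s]\n",
    round(x$r_min, digits), round(x$r_max, digits),
    round(x$r2_min, digits), round(x$r2_max, digits),
    signif(x$slope_min, digits), signif(x$slope_max, digits),
    signif(x$p_min, digits), signif(x$p_max, digits)
  ))
  cat(sprintf("all r positive: %s; all slopes p < %s: %s\n",
              x$all_positive, x$p_threshold, x$all_significant))
  invisible(x)
}
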