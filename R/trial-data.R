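# Trial-level data model: one row per randomized controlled trial, holding the
# quantities extractable from a publication (per-arm Ns, hazard ratios with
# 95% CIs for PFS1/PFS2/OS at initial and long-term reporting, per-arm median
# PFS2/OS, event counts and planned event counts, crossover percentage, and
# design flags). Missingness is explicit (NA in memory, "NR" on disk).

.hr_endpoints <- c("pfs1", "pfs2", "os_initial", "os_longterm")

.hr_columns <- function() {
  as.vector(vapply(
    .hr_endpoints,
    function(e) paste0("hr_", e, c("", "_low", "_high")),
    character(3)
  ))
}

#' Column schema of a trial set
#'
#' Returns the documented column names of the trial-level table used across
#' the package. Hazard ratios are stored as point estimate plus 95% CI bounds
#' (`hr_<endpoint>`, `hr_<endpoint>_low`, `hr_<endpoint>_high`) for endpoints
#' `pfs1`, `pfs2`, `os_initial` and `os_longterm`. Percentages are on the
#' 0-100 scale; medians are in months.
#'
#' @return Character vector of column names.
#' @export
trial_columns <- function() {
  c(
    "trial_id", "year", "subtype", "prior_lines", "pfs2_in_protocol",
    "pfs2_designation", "pfs2_line", "n_intervention", "n_control",
    .hr_columns(),
    "median_pfs2_int", "median_pfs2_ctrl", "median_os_int", "median_os_ctrl",
    "os_events", "os_denominator", "os_planned_events",
    "pfs2_events", "pfs2_denominator",
    "os_events_longterm", "os_denominator_longterm",
    "crossover_pct", "longterm_available"
  )
}

.subtype_levels <- c("HRpos_HER2neg", "HER2pos", "HER2neg_mixed")
.designation_levels <- c("primary", "secondary", "exploratory")
.line_levels <- c("second_line", "later_line")

#' Construct an empty trial set
#'
#' @param provenance Character label recording where the records came from.
#' @return A zero-row `trial_set` data frame with the full column schema.
#' @export
empty_trial_set <- function(provenance = "empty") {
  cols <- trial_columns()
  df <- as.data.frame(
    setNames(rep(list(logical(0)), length(cols)), cols),
    stringsAsFactors = FALSE
  )
  as_trial_set(df, provenance = provenance, validate = FALSE)
}

#' Mark a data frame as a trial set
#'
#' Fills absent optional columns with NA, validates record-level invariants
#' and attaches the `trial_set` class and a provenance attribute.
#'
#' @param df Data frame with at least `trial_id`, `n_intervention`,
#'   `n_control`.
#' @param provenance Character label (file path, `"fixture:table1"`, ...).
#' @param validate Check invariants (default TRUE).
#' @param strict If TRUE (default) invariant violations are errors; if FALSE
#'   they are warnings and offending rows are kept.
#' @return A `trial_set` data frame.
#' @export
as_trial_set <- function(df, provenance = "user", validate = TRUE,
                         strict = TRUE) {
  stopifnot(is.data.frame(df))
  required <- c("trial_id", "n_intervention", "n_control")
  missing_req <- setdiff(required, names(df))
  if (length(missing_req) > 0 && nrow(df) > 0) {
    stop("trial set lacks required columns: ", paste(missing_req, collapse = ", "))
  }
  char_cols <- c("trial_id", "subtype", "prior_lines", "pfs2_in_protocol",
                 "pfs2_designation", "pfs2_line")
  for (col in setdiff(trial_columns(), names(df))) df[[col]] <- NA
  df <- df[, trial_columns(), drop = FALSE]
  # coerce each column to its schema type (all-NA columns default to logical)
  for (col in trial_columns()) {
    df[[col]] <- if (col %in% char_cols) {
      as.character(df[[col]])
    } else if (col == "longterm_available") {
      as.logical(df[[col]])
    } else {
      as.numeric(df[[col]])
    }
  }
  rownames(df) <- NULL
  if (validate && nrow(df) > 0) validate_trials(df, strict = strict)
  structure(df, class = c("trial_set", "data.frame"), provenance = provenance)
}

#' Validate trial-level records
#'
#' Checks the invariants every record must satisfy: unique trial ids, positive
#' arm sizes, positive hazard ratios with `ci_low <= hr <= ci_high`,
#' non-negative event counts, crossover percentage within 0-100. Information
#' fractions above 100% are legitimate and never flagged.
#'
#' @param df Trial set or plain data frame with the schema columns.
#' @param strict Errors (TRUE) or warnings (FALSE) on violation.
#' @return Invisibly TRUE; signals row-addressed messages otherwise.
#' @export
validate_trials <- function(df, strict = TRUE) {
  problems <- character(0)
  note <- function(rows, msg) {
    if (length(rows) > 0) {
      problems <<- c(problems, sprintf(
        "row %s (%s): %s", rows, df$trial_id[rows], msg
      ))
    }
  }
  if (anyDuplicated(df$trial_id)) {
    dup <- unique(df$trial_id[duplicated(df$trial_id)])
    problems <- c(problems, paste0("duplicate trial_id: ", paste(dup, collapse = ", ")))
  }
  bad_n <- which(!is.na(df$n_intervention) & df$n_intervention < 1 |
                 !is.na(df$n_control) & df$n_control < 1 |
                 is.na(df$n_intervention) | is.na(df$n_control))
  note(bad_n, "arm sizes must be present and >= 1")
  for (ep in .hr_endpoints) {
    hr <- df[[paste0("hr_", ep)]]
    lo <- df[[paste0("hr_", ep, "_low")]]
    hi <- df[[paste0("hr_", ep, "_high")]]
    note(which(!is.na(hr) & hr <= 0), paste0("hr_", ep, " must be > 0"))
    note(which(!is.na(lo) & !is.na(hi) & lo > hi),
         paste0("hr_", ep, " CI has ci_low > ci_high"))
    note(which(!is.na(hr) & !is.na(lo) & lo > hr),
         paste0("hr_", ep, " point estimate below ci_low"))
    note(which(!is.na(hr) & !is.na(hi) & hr > hi),
         paste0("hr_", ep, " point estimate above ci_high"))
    note(which(!is.na(lo) & lo <= 0), paste0("hr_", ep, "_low must be > 0"))
  }
  for (col in c("os_events", "os_planned_events", "pfs2_events",
                "os_events_longterm")) {
    note(which(!is.na(df[[col]]) & df[[col]] < 0),
         paste0(col, " must be >= 0"))
  }
  note(which(!is.na(df$crossover_pct) &
               (df$crossover_pct < 0 | df$crossover_pct > 100)),
       "crossover_pct must lie in [0, 100]")
  if (length(problems) > 0) {
    msg <- paste0("invalid trial records:\n  ", paste(problems, collapse = "\n  "))
    if (strict) stop(msg) else warning(msg)
  }
  invisible(TRUE)
}

#' Read a trial-level extraction table
#'
#' Reads a delimited (comma or tab) UTF-8 table with the column schema of
#' [trial_columns()], one row per trial. Missing values are encoded by a
#' token, `"NR"` ("not reported") by default, matching how trial publications
#' print unavailable quantities.
#'
#' @param path Path to the file.
#' @param delim Field delimiter; `NULL` (default) infers from the extension
#'   (`.tsv`/`.tab` -> tab, otherwise comma).
#' @param na_token Missing-value token (default `"NR"`).
#' @param strict Reject (TRUE) or warn (FALSE) on invariant violations.
#' @return A `trial_set` data frame; zero rows (with a warning) if the file
#'   holds only a header.
#' @export
read_trials <- function(path, delim = NULL, na_token = "NR", strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(
    path, header = TRUE, sep = delim, quote = "\"",
    na.strings = c(na_token, "NA", ""), stringsAsFactors = FALSE,
    fileEncoding = "UTF-8", check.names = FALSE
  )
  if (nrow(df) == 0) {
    warning("input table has a header but no data rows: ", path)
    return(empty_trial_set(provenance = path))
  }
  num_cols <- setdiff(
    trial_columns(),
    c("trial_id", "subtype", "prior_lines", "pfs2_in_protocol",
      "pfs2_designation", "pfs2_line", "longterm_available")
  )
  for (col in intersect(num_cols, names(df))) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  if ("longterm_available" %in% names(df)) {
    df$longterm_available <- as.logical(df$longterm_available)
  }
  as_trial_set(df, provenance = path, strict = strict)
}

#' Write a trial set to a delimited file
#'
#' Inverse of [read_trials()]: missing values are written as the token, and
#' `read_trials(write_trials(x))` reproduces `x` up to numeric formatting.
#'
#' @param trials A `trial_set`.
#' @param path Output path; `.tsv` extension selects tab delimiting.
#' @param na_token Token for missing values (default `"NR"`).
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, na_token = "NR") {
  delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- as.data.frame(trials)
  utils::write.table(
    df, path, sep = delim, na = na_token, row.names = FALSE,
    quote = TRUE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Restrict a trial set to records complete for an analysis
#'
#' Implements per-analysis eligibility: only trials with all `required_fields`
#' non-missing are kept; exclusions are reported via a message so each
#' analysis's n is reproducible.
#'
#' @param trials A `trial_set`.
#' @param required_fields Character vector of schema column names that must be
#'   present (non-NA). Requiring an endpoint's HR point estimate, e.g.
#'   `"hr_pfs2"`, is the usual usage.
#' @param min_n Minimum surviving records below which an "insufficient trials"
#'   error is raised; use 0 to disable (default 0).
#' @param quiet Suppress the exclusion message.
#' @return The filtered `trial_set`.
#' @export
analysis_subset <- function(trials, required_fields, min_n = 0, quiet = FALSE) {
  stopifnot(inherits(trials, "trial_set") || is.data.frame(trials))
  unknown <- setdiff(required_fields, trial_columns())
  if (length(unknown) > 0) {
    stop("unknown field(s): ", paste(unknown, collapse = ", "))
  }
  if (nrow(trials) == 0) {
    if (min_n > 0) stop("insufficient trials: 0 remain, need >= ", min_n)
    return(trials)
  }
  if (length(required_fields) == 0) return(trials)
  keep <- rep(TRUE, nrow(trials))
  why <- rep("", nrow(trials))
  for (f in required_fields) {
    miss <- is.na(trials[[f]])
    why[miss & keep] <- paste0("missing ", f)
    keep <- keep & !miss
  }
  if (!quiet && any(!keep)) {
    message(
      "excluded ", sum(!keep), " trial(s): ",
      paste(sprintf("%s (%s)", trials$trial_id[!keep], why[!keep]),
            collapse = "; ")
    )
  }
  out <- trials[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (min_n > 0 && nrow(out) < min_n) {
    stop("insufficient trials: ", nrow(out), " remain, need >= ", min_n)
  }
  attr(out, "provenance") <- attr(trials, "provenance")
  out
}

#' Built-in fixture of the 18 included breast-cancer trials
#'
#' The study-characteristics table of the 18 randomized breast-cancer trials
#' the analyses target: publication year, disease subtype, prior treatment
#' lines at entry, whether PFS2 was protocol-specified and its endpoint
#' designation, per-arm sample sizes, OS events over the maturity denominator,
#' planned OS events (reconstructed from the printed information-fraction
#' denominator), PFS2 events over denominator, and availability of long-term
#' OS follow-up. Hazard ratios are not part of this table; they are loaded,
#' when available, from a user-supplied extraction file via [read_trials()].
#'
#' Printed values are stored verbatim per column even where the source table
#' is internally inconsistent (e.g. Pearl's OS maturity denominator 305 versus
#' arm sizes summing to 448); event/denominator quotients, not the printed
#' percentages, are authoritative for all arithmetic.
#'
#' @return A `trial_set` with 18 records, provenance `"fixture:table1"`.
#' @export
table1_fixture <- function() {
  rec <- function(trial_id, year, subtype, prior_lines, in_protocol,
                  designation, n_int, n_ctrl, os_ev, os_den, os_plan,
                  pfs2_ev, pfs2_den, longterm) {
    data.frame(
      trial_id = trial_id, year = year, subtype = subtype,
      prior_lines = prior_lines, pfs2_in_protocol = in_protocol,
      pfs2_designation = designation,
      pfs2_line = if (identical(prior_lines, "0")) "second_line" else "later_line",
      n_intervention = n_int, n_control = n_ctrl,
      os_events = os_ev, os_denominator = os_den, os_planned_events = os_plan,
      pfs2_events = pfs2_ev, pfs2_denominator = pfs2_den,
      longterm_available = longterm,
      stringsAsFactors = FALSE
    )
  }
  df <- rbind(
    rec("SERENA-6",          2025, "HRpos_HER2neg", "1",      "yes", "secondary",   157, 158,  39, 315, 165,  85, 315, FALSE),
    rec("DESTINY-Breast09",  2025, "HER2pos",       "0",      NA,    NA,            383, 387, 126, 770,  NA, 193, 770, FALSE),
    rec("TROPION-Breast01",  2025, "HRpos_HER2neg", "1 or 2", "yes", "secondary",   365, 367, 171, 732, 444, 238, 732, FALSE),
    rec("SONIA",             2024, "HRpos_HER2neg", "0",      "yes", "primary",     524, 526, 372, 1050, NA, 591, 1050, FALSE),
    rec("INAVO120",          2024, "HRpos_HER2neg", "0",      "yes", "exploratory", 161, 164,  97, 325, 153,  NA,  NA, TRUE),
    rec("CAPItello-291",     2023, "HRpos_HER2neg", "1 or 2", "yes", "secondary",   355, 353, 195, 708, 492, 383, 708, FALSE),
    rec("DESTINY-Breast03",  2023, "HER2pos",       ">1",     "yes", "exploratory", 261, 263, 169, 524, 250,  NA,  NA, TRUE),
    rec("DESTINY-Breast02",  2023, "HER2pos",       ">1",     "yes", "exploratory", 406, 202, 230, 608, 434,  NA,  NA, FALSE),
    rec("Pearl",             2022, "HRpos_HER2neg", "1",      "no",  "exploratory", 149, 299, 171, 300, 152, 230, 305, FALSE),
    rec("MONALEESA-3",       2021, "HRpos_HER2neg", "0",      "yes", "exploratory", 237, 128, 364, 726, 273, 428, 726, TRUE),
    rec("MONARCH-3",         2021, "HRpos_HER2neg", "0",      "no",  "exploratory", 328, 165,  NA,  NA,  NA,  NA,  NA, TRUE),
    rec("MONARCH-2",         2020, "HRpos_HER2neg", "1",      "no",  "exploratory", 446, 223, 338, 669, 441, 457, 669, FALSE),
    rec("BROCAD3",           2020, "HER2neg_mixed", "2",      "no",  "secondary",   337, 172, 254, 509, 357, 310, 509, TRUE),
    rec("MONALEESA-7",       2019, "HRpos_HER2neg", "1",      "no",  "exploratory", 335, 337, 192, 672, 252, 287, 672, TRUE),
    rec("PALOMA-3",          2018, "HRpos_HER2neg", ">1",     "no",  "exploratory", 347, 174, 310, 521, 198,  NA,  NA, TRUE),
    rec("OlympiAD",          2017, "HER2neg_mixed", "1",      "yes", "secondary",   205,  97, 140, 302, 190,  NA,  NA, TRUE),
    rec("TANIA",             2014, "HER2neg_mixed", "0",      "yes", "primary",     247, 247, 200, 494,  NA, 407, 494, TRUE),
    rec("VITAL",             2014, "HER2pos",       "1",      "no",  "exploratory",  75,  37,  35, 112,  NA,  NA,  NA, TRUE)
  )
  as_trial_set(df, provenance = "fixture:table1")
}

#' Total randomized patients per trial
#'
#' @param trials A `trial_set`.
#' @return Numeric vector `n_intervention + n_control`.
#' @export
total_n <- function(trials) {
  trials$n_intervention + trials$n_control
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf(
    "Trial set: %d trial(s) [%s]\n",
    nrow(x), attr(x, "provenance") %||% "unknown"
  ))
  print(as.data.frame(x)[, c("trial_id", "year", "subtype",
                             "n_intervention", "n_control")], ...)
  invisible(x)
}
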