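#' Apply questionnaire exclusion filters
#'
#' Screens respondents in four ordered steps, each record being counted under
#' the first rule it fails:
#'
#' 1. `missing_gt_5pct` — more than 5% of the questionnaire fields (the twelve
#'    covariates plus all 29 scored items and the reverse check) are missing;
#' 2. `logical_inconsistency` — PHQ-9 item 1 and its reverse-worded pair are
#'    both "not at all" (0) or both "nearly every day" (3);
#' 3. `multiple_selection` — multiple answers to a single-choice item
#'    (possible only in raw form exports; carried on the `qc_flag` column);
#' 4. `irrelevant_or_contradictory` — answers inconsistent with the question
#'    content (likewise carried on `qc_flag`).
#'
#' @param records Cohort tibble from [read_survey_table()] or
#'   [generate_cohort()].
#' @param verbose Emit one message per exclusion reason.
#' @return A list with `records` (the kept rows, original order) and `report`,
#'   a `qc_report` with fields `n_collected`, `n_excluded_by_reason`,
#'   `n_valid` and `effective_response_rate`.
#' @export
apply_exclusion_filters <- function(records, verbose = FALSE) {
  reasons <- c("missing_gt_5pct", "logical_inconsistency",
               "multiple_selection", "irrelevant_or_contradictory")
  n <- nrow(records)
  if (n == 0L) {
    report <- new_qc_report(0L, setNames(integer(4), reasons))
    return(list(records = records, report = report))
  }
  qfields <- questionnaire_cols()
  present <- intersect(qfields, names(records))
  frac_missing <- rowMeans(is.na(records[, present, drop = FALSE]))
  d1 <- records[[phq9_cols()[1]]]
  rev <- records[[phq9_reverse_col()]]
  inconsistent <- !is.na(d1) & !is.na(rev) & ((d1 == 0L & rev == 0L) | (d1 == 3L & rev == 3L))
  flag <- if ("qc_flag" %in% names(records)) as.character(records$qc_flag) else rep("none", n)
  flag[is.na(flag)] <- "none"

  reason <- rep(NA_character_, n)
  reason[flag == "irrelevant_or_contradictory"] <- "irrelevant_or_contradictory"
  reason[flag == "multiple_selection"] <- "multiple_selection"
  reason[inconsistent] <- "logical_inconsistency"
  reason[frac_missing > 0.05] <- "missing_gt_5pct"

  counts <- setNames(vapply(reasons, function(r) sum(reason == r, na.rm = TRUE), 0L), reasons)
  kept <- records[is.na(reason), , drop = FALSE]
  report <- new_qc_report(n, counts)
  if (verbose) {
    for (r in reasons[counts > 0L]) {
      message(sprintf("excluded %d record(s): %s", counts[[r]], r))
    }
  }
  list(records = kept, report = report)
}

new_qc_report <- function(n_collected, counts) {
  structure(
    list(
      n_collected = as.integer(n_collected),
      n_excluded_by_reason = counts,
      n_valid = as.integer(n_collected - sum(counts)),
      effective_response_rate =
        if (n_collected > 0) (n_collected - sum(counts)) / n_collected else NA_real_
    ),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Questionnaire QC report\n")
  cat(sprintf("  collected: %d\n", x$n_collected))
  for (r in names(x$n_excluded_by_reason)) {
    cat(sprintf("  excluded (%s): %d\n", r, x$n_excluded_by_reason[[r]]))
  }
  cat(sprintf("  valid: %d (effective response rate %.2f%%)\n",
              x$n_valid, 100 * x$effective_response_rate))
  invisible(x)
}

#' @export
format.qc_report <- function(x, ...) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
}

#' Write a QC report as JSON
#' @param report A `qc_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
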