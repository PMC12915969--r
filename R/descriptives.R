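#' Median and interquartile range
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7), the common software default; the rule is
#' fixed here so published medians/IQRs can be audited.
#'
#' @param x Non-empty numeric vector (missing values dropped).
#' @return Named numeric vector `c(median = , iqr = )`.
#' @export
summarize_median_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("summarize_median_iqr: empty input")
  c(median = median(x), iqr = unname(quantile(x, 0.75) - quantile(x, 0.25)))
}

#' Nonparametric group comparison of an instrument total
#'
#' Two groups are compared with the Mann-Whitney U test (U reported for the
#' first-listed group; normal approximation with tie and continuity
#' correction for larger groups, exact enumeration for small tie-free ones),
#' three or more with the tie-corrected Kruskal-Wallis H test. Empty groups
#' are dropped with a warning. When every observation is tied the statistic
#' is 0 with p = 1 by convention.
#'
#' @param outcome Numeric vector of scores.
#' @param group Factor (or coercible) of group labels, same length.
#' @param outcome_name,grouping Optional names recorded in the result.
#' @return A `group_comparison` list: `test` (`"mann_whitney_U"` or
#'   `"kruskal_wallis_H"`), `statistic`, `p_value`, and `per_group`, a tibble
#'   of label, n, median and IQR.
#' @export
compare_groups <- function(outcome, group, outcome_name = "outcome",
                           grouping = "group") {
  stopifnot(length(outcome) == length(group))
  keep <- !is.na(outcome) & !is.na(group)
  outcome <- outcome[keep]
  if (!is.factor(group)) group <- factor(group)
  group <- group[keep]
  tab <- table(group)
  if (any(tab == 0L)) {
    warning("dropping empty group level(s): ",
            paste(names(tab)[tab == 0L], collapse = ", "))
    group <- droplevels(group)
    tab <- table(group)
  }
  if (nlevels(group) < 2L) stop("compare_groups needs at least 2 non-empty groups")

  per_group <- dplyr::bind_rows(lapply(levels(group), function(l) {
    xs <- outcome[group == l]
    s <- summarize_median_iqr(xs)
    tibble::tibble(label = l, n = length(xs), median = s[["median"]], iqr = s[["iqr"]])
  }))

  all_tied <- length(unique(outcome)) == 1L
  if (nlevels(group) == 2L) {
    test <- "mann_whitney_U"
    if (all_tied) {
      statistic <- prod(tab) / 2
      p <- 1
    } else {
      wt <- suppressWarnings(
        wilcox.test(outcome[group == levels(group)[1]],
                    outcome[group == levels(group)[2]], correct = TRUE)
      )
      statistic <- unname(wt$statistic)  # U for the first-listed group
      p <- wt$p.value
    }
  } else {
    test <- "kruskal_wallis_H"
    if (all_tied) {
      statistic <- 0
      p <- 1
    } else {
      kt <- kruskal.test(outcome, group)
      statistic <- unname(kt$statistic)
      p <- kt$p.value
    }
  }
  structure(
    list(outcome = outcome_name, grouping = grouping, test = test,
         statistic = statistic, p_value = min(1, p), per_group = per_group),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s by %s: %s = %.4g, p = %.4g\n", x$outcome, x$grouping,
              if (x$test == "mann_whitney_U") "U" else "H",
              x$statistic, x$p_value))
  print(x$per_group)
  invisible(x)
}

#' Descriptive comparison table across all covariates
#'
#' For each covariate and each instrument total, tabulates per-level n, %,
#' median and IQR together with the appropriate nonparametric test, in the
#' shape of a standard sociodemographic characteristics table.
#'
#' @param records Post-QC cohort tibble (for the covariates).
#' @param scored Imputed tibble from [score_instruments()].
#' @param covariates Covariate names; defaults to all twelve.
#' @return A long tibble: covariate, level, n, pct, outcome, median, iqr,
#'   test, statistic, p_value.
#' @export
table_one <- function(records, scored, covariates = covariate_cols()) {
  outcomes <- c(psqi_total = "psqi_total", phq9_total = "phq9_total",
                nsbq_total = "nsbq_total")
  rows <- list()
  for (cv in covariates) {
    g <- droplevels(factor(records[[cv]]))
    for (oc in outcomes) {
      cmp <- compare_groups(scored[[oc]], g, outcome_name = oc, grouping = cv)
      pg <- cmp$per_group
      pg$pct <- 100 * pg$n / sum(pg$n)
      pg <- tibble::tibble(covariate = cv, level = pg$label, n = pg$n,
                           pct = pg$pct, outcome = oc, median = pg$median,
                           iqr = pg$iqr, test = cmp$test,
                           statistic = cmp$statistic, p_value = cmp$p_value)
      rows[[length(rows) + 1L]] <- pg
    }
  }
  dplyr::bind_rows(rows)
}
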