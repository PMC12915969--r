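#' Score the three instruments
#'
#' Computes instrument totals and screening flags for every respondent.
#' A total is the exact sum of its constituent items — PSQI global score
#' (0-21, components C1-C7), PHQ-9 total (0-27, items 1-9; the reverse-worded
#' check item is never scored), NSBQ total (12-60) — and is left missing when
#' any constituent item is missing, pending total-level imputation with
#' [impute_total_median()]. Screening flags follow the validated cutoffs:
#' PSQI > 7 screens poor sleep quality, PHQ-9 >= 10 screens moderate-to-severe
#' depressive symptoms.
#'
#' @param records Cohort tibble (post-QC).
#' @return A tibble with `participant_id`, `psqi_total`, `phq9_total`,
#'   `nsbq_total`, `poor_sleep`, `depr_positive`, and per-total `*_imputed`
#'   flags (all `FALSE` here).
#' @export
score_instruments <- function(records) {
  sum_complete <- function(cols) {
    m <- as.matrix(records[, cols, drop = FALSE])
    storage.mode(m) <- "double"
    s <- rowSums(m)           # NA whenever any item is missing
    s
  }
  out <- tibble::tibble(
    participant_id = records$participant_id,
    psqi_total = sum_complete(psqi_cols()),
    phq9_total = sum_complete(phq9_cols()),
    nsbq_total = sum_complete(nsbq_cols())
  )
  out$poor_sleep <- out$psqi_total > 7
  out$depr_positive <- out$phq9_total >= 10
  out$psqi_imputed <- FALSE
  out$phq9_imputed <- FALSE
  out$nsbq_imputed <- FALSE
  out
}

#' Median-impute missing instrument totals
#'
#' Missing totals are replaced by the median of the observed totals (the
#' median is preferred over the mean because the score distributions are
#' skewed). Screening flags are recomputed from the imputed totals and the
#' per-total imputation flag is set.
#'
#' @param scored Tibble from [score_instruments()].
#' @param which One of `"psqi"`, `"phq9"`, `"nsbq"`.
#' @param verbose Message the number of imputations.
#' @return The scored tibble with the chosen total imputed.
#' @export
impute_total_median <- function(scored, which = c("psqi", "phq9", "nsbq"),
                                verbose = FALSE) {
  which <- match.arg(which)
  col <- paste0(which, "_total")
  x <- scored[[col]]
  miss <- is.na(x)
  if (all(miss)) stop("cannot impute: all ", col, " values are missing")
  if (any(miss)) {
    med <- median(x[!miss])
    scored[[col]][miss] <- med
    scored[[paste0(which, "_imputed")]][miss] <- TRUE
    if (verbose) message(sprintf("imputed %d missing %s value(s) with median %g",
                                 sum(miss), col, med))
  }
  scored$poor_sleep <- scored$psqi_total > 7
  scored$depr_positive <- scored$phq9_total >= 10
  scored
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a set of items:
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i s_i^2}{s_T^2}\right)}
#' where \eqn{s_i^2} are the item variances and \eqn{s_T^2} the variance of
#' the item sums, all with the sample (n-1) denominator.
#'
#' @param items Numeric matrix or data frame, respondents in rows, items in
#'   columns; at least 2 items, 3 respondents, no missing values.
#' @return The alpha coefficient (scalar).
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  storage.mode(m) <- "double"
  if (ncol(m) < 2L) stop("cronbach_alpha needs at least 2 items")
  if (nrow(m) < 3L) stop("cronbach_alpha needs at least 3 respondents")
  if (anyNA(m)) stop("cronbach_alpha requires a complete item matrix")
  k <- ncol(m)
  total_var <- var(rowSums(m))
  if (total_var == 0) stop("total score has zero variance; alpha undefined")
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
}

#' Harman single-factor test for common method bias
#'
#' Principal-component analysis of the standardized item matrix; the
#' proportion of total variance captured by the first component is compared
#' against the conventional 40% threshold. A first factor holding less than
#' 40% of the variance indicates that a single common method factor does not
#' dominate the item covariance.
#'
#' @param items Complete numeric item matrix (all instruments' items pooled).
#' @return A list with `proportion` (first-PC variance share, in (0, 1]) and
#'   `exceeds_threshold` (`TRUE` when the share exceeds 0.40).
#' @export
harman_single_factor <- function(items) {
  m <- as.matrix(items)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("harman_single_factor requires a complete item matrix")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    stop("constant item column(s) cannot be standardized: ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  prop <- pc$sdev[1]^2 / ncol(m)
  list(proportion = prop, exceeds_threshold = prop > 0.40)
}

#' Complete the item matrix for item-level analyses
#'
#' The item-level analyses (reliability, common-method-bias screen, and the
#' symptom network) require a complete item matrix. Isolated missing item
#' cells surviving QC (at most 5% of a record's fields) are filled with the
#' item's median across respondents; instrument totals are never touched
#' here (see [impute_total_median()]).
#'
#' @param records Post-QC cohort tibble.
#' @param verbose Message the number of filled cells.
#' @return The cohort with complete item columns.
#' @export
complete_items <- function(records, verbose = FALSE) {
  n_filled <- 0L
  for (col in setdiff(item_cols(), phq9_reverse_col())) {
    v <- records[[col]]
    miss <- is.na(v)
    if (any(miss)) {
      v[miss] <- median(v[!miss])
      records[[col]] <- v
      n_filled <- n_filled + sum(miss)
    }
  }
  if (verbose && n_filled > 0L) {
    message(sprintf("filled %d missing item cell(s) with item medians", n_filled))
  }
  records
}

#' @importFrom stats prcomp
NULL
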