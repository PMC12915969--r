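test_that("a clean CSV round-trips to records without warnings", {
  df <- make_cohort_df(3)
  path <- write_cohort_csv(df)
  expect_no_warning(rec <- read_survey_table(path))
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$participant_id, df$participant_id)
  expect_equal(rec$PSQI_C1, df$PSQI_C1)  # row order preserved
})

test_that("out-of-range item cells become missing with a warning", {
  df <- make_cohort_df(3)
  df$PSQI_C2[2] <- 7L
  df$NSBQ_4[1] <- 0L
  path <- write_cohort_csv(df)
  expect_warning(rec <- read_survey_table(path), "out-of-range")
  expect_true(is.na(rec$PSQI_C2[2]))
  expect_true(is.na(rec$NSBQ_4[1]))
  expect_equal(rec$PSQI_C2[-2], df$PSQI_C2[-2])
})

test_that("schema maps bind arbitrary headers and missing columns error", {
  df <- make_cohort_df(3)
  names(df)[names(df) == "D_5"] <- "phq_item_5"
  path <- write_cohort_csv(df)
  expect_error(read_survey_table(path), "D_5")
  rec <- read_survey_table(path, schema_map = c(D_5 = "phq_item_5"))
  expect_equal(rec$D_5, df$phq_item_5)
})

test_that("reverse-pair inconsistency rule excludes exactly the flagged patterns", {
  df <- make_cohort_df(4)
  df$D_1 <- c(0L, 0L, 3L, 2L)
  df$D_1R <- c(0L, 3L, 3L, 2L)
  out <- apply_exclusion_filters(df)
  # rows 1 (both "not at all") and 3 (both "nearly every day") are dropped
  expect_equal(out$report$n_excluded_by_reason[["logical_inconsistency"]], 2L)
  expect_equal(out$records$participant_id, df$participant_id[c(2, 4)])
})

test_that("exclusion reasons follow the documented priority order", {
  df <- make_cohort_df(2)
  # row 1 both misses >5% of fields and has an inconsistent reverse pair:
  # counted once, under the missingness rule
  df$D_1[1] <- 0L; df$D_1R[1] <- 0L
  df[1, psqi_cols()[1:4]] <- NA_integer_
  out <- apply_exclusion_filters(df)
  expect_equal(out$report$n_excluded_by_reason[["missing_gt_5pct"]], 1L)
  expect_equal(out$report$n_excluded_by_reason[["logical_inconsistency"]], 0L)
  expect_equal(out$report$n_valid + sum(out$report$n_excluded_by_reason),
               out$report$n_collected)
})

test_that("QC is idempotent and tolerates empty input", {
  coh <- generate_cohort(synthetic_config(n_valid = 120L,
                                          planted_qc = c(logical_inconsistency = 6L,
                                                         irrelevant_or_contradictory = 4L,
                                                         multiple_selection = 2L),
                                          planted_missing_totals = 2L),
                         seed = 5)
  once <- apply_exclusion_filters(coh$records)
  twice <- apply_exclusion_filters(once$records)
  expect_equal(twice$records, once$records)
  expect_equal(sum(twice$report$n_excluded_by_reason), 0L)
  expect_equal(once$report$n_valid, 120L)

  empty <- apply_exclusion_filters(coh$records[0, ])
  expect_equal(empty$report$n_collected, 0L)
  expect_equal(nrow(empty$records), 0L)
})

test_that("instrument totals are exact item sums with the documented cutoffs", {
  df <- make_cohort_df(3)
  df[1, psqi_cols()] <- as.list(rep(0L, 7))
  df[2, psqi_cols()] <- as.list(c(2L, 1L, 1L, 1L, 1L, 1L, 1L))
  df[3, phq9_cols()] <- as.list(rep(3L, 9))
  sc <- score_instruments(df)
  expect_equal(sc$psqi_total[1], 0)
  expect_false(sc$poor_sleep[1])
  expect_equal(sc$psqi_total[2], 8)   # strictly above the >7 screen
  expect_true(sc$poor_sleep[2])
  expect_equal(sc$phq9_total[3], 27)
  expect_true(sc$depr_positive[3])
  expect_equal(sc$nsbq_total, rowSums(df[, nsbq_cols()]))
})

test_that("scoring is additive and permutation-invariant within an instrument", {
  df <- make_cohort_df(20, seed = 7)
  sc1 <- score_instruments(df)
  perm <- df
  perm[, psqi_cols()] <- df[, sample(psqi_cols())]
  perm[, nsbq_cols()] <- df[, sample(nsbq_cols())]
  sc2 <- score_instruments(perm)
  expect_equal(sc2$psqi_total, sc1$psqi_total)
  expect_equal(sc2$nsbq_total, sc1$nsbq_total)
})

test_that("missing items leave the total missing until median imputation", {
  df <- make_cohort_df(4)
  df$PSQI_C3[3] <- NA_integer_
  sc <- score_instruments(df)
  expect_true(is.na(sc$psqi_total[3]))
  sc$psqi_total[-3] <- c(4, 9, 9)
  imp <- impute_total_median(sc, "psqi")
  expect_equal(imp$psqi_total[3], 9)   # median of {4, 9, 9}
  expect_true(imp$psqi_imputed[3])
  expect_false(any(imp$psqi_imputed[-3]))

  # identity when nothing is missing
  expect_equal(impute_total_median(imp, "psqi"), imp)
  sc$psqi_total <- NA_real_
  expect_error(impute_total_median(sc, "psqi"), "all")
})

test_that("Cronbach's alpha matches an independent covariance-based oracle", {
  set.seed(31)
  # perfectly congeneric limit: duplicated items
  dup <- matrix(rep(rnorm(50), 4), ncol = 4)
  expect_equal(cronbach_alpha(dup), 1)
  # independent items: alpha near zero
  ind <- matrix(rnorm(2 * 10000), ncol = 2)
  expect_lt(abs(cronbach_alpha(ind)), 0.05)
  # random ordinal matrices against the oracle
  for (k in c(3, 5, 8)) {
    m <- matrix(sample(0:3, 40 * k, replace = TRUE), ncol = k)
    m[, 1] <- m[, 2]  # induce structure so alpha is not degenerate
    expect_equal(cronbach_alpha(m), alpha_oracle(m), tolerance = 1e-12)
  }
  expect_error(cronbach_alpha(matrix(1, 10, 3)), "zero variance")
})

test_that("Harman first-factor proportion equals the top eigenvalue share", {
  set.seed(41)
  common <- rnorm(200)
  rank1 <- sapply(1:6, function(i) i * common)
  expect_equal(harman_single_factor(rank1)$proportion, 1.0, tolerance = 1e-10)
  expect_true(harman_single_factor(rank1)$exceeds_threshold)

  ind <- matrix(rnorm(20000 * 10), ncol = 10)
  h <- harman_single_factor(ind)
  expect_lt(abs(h$proportion - 0.1), 0.015)
  expect_false(h$exceeds_threshold)

  # eigenvalue oracle on a small correlated fixture
  m <- matrix(rnorm(100 * 5), ncol = 5) + 0.8 * common[1:100]
  ev <- eigen(cor(m), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(harman_single_factor(m)$proportion, ev[1] / 5, tolerance = 1e-12)

  m[, 2] <- 1
  expect_error(harman_single_factor(m), "constant")
})
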