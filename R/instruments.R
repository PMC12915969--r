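#' Instrument and covariate column definitions
#'
#' Canonical column names for the three instruments and the sociodemographic
#' covariates used throughout the pipeline. The Pittsburgh Sleep Quality Index
#' (PSQI) contributes 7 component scores (0-3), the Patient Health
#' Questionnaire-9 (PHQ-9) 9 items (0-3) plus one reverse-worded consistency
#' check paired with item 1, and the Nurse Safety Behavior Questionnaire
#' (NSBQ) 12 items (1-5).
#'
#' @return Character vectors of canonical column names.
#' @name instrument_columns
NULL

#' @rdname instrument_columns
#' @export
psqi_cols <- function() paste0("PSQI_C", 1:7)

#' @rdname instrument_columns
#' @export
phq9_cols <- function() paste0("D_", 1:9)

#' @rdname instrument_columns
#' @export
nsbq_cols <- function() paste0("NSBQ_", 1:12)

#' Name of the reverse-worded PHQ-9 consistency-check column
#' @export
phq9_reverse_col <- function() "D_1R"

#' @rdname instrument_columns
#' @export
covariate_cols <- function() {
  c("gender", "age_band", "ethnicity", "education", "hospital_level",
    "work_experience_band", "professional_title", "shift_pattern",
    "night_shift_band", "off_days_band", "marital_status", "children_band")
}

#' All questionnaire field columns used by the missingness rule
#' @export
questionnaire_cols <- function() {
  c(covariate_cols(), psqi_cols(), phq9_cols(), phq9_reverse_col(), nsbq_cols())
}

#' The 17 symptom-network node names, in canonical order
#'
#' Seven PSQI components, nine PHQ-9 items, and the NSBQ total score.
#' @export
network_nodes <- function() c(psqi_cols(), phq9_cols(), "NSBQ_total")

#' Closed category-label sets for the sociodemographic covariates
#'
#' Returns a named list; each element is the ordered vector of legal labels
#' for one covariate, the first label being the dummy-coding reference level.
#' @export
covariate_levels <- function() {
  list(
    gender = c("Male", "Female"),
    age_band = c("20-29", "30-39", "40-49", ">=50"),
    ethnicity = c("Han", "Zhuang", "Other"),
    education = c("Vocational high school", "Associate degree",
                  "Bachelor's degree", "Master's degree or higher"),
    hospital_level = c("Urban hospital", "County-level hospital"),
    work_experience_band = c("<=5", "5-10", "10-15", "15-20", ">20"),
    professional_title = c("Junior and below", "Intermediate", "Senior"),
    shift_pattern = c("DN", "APN", "Other"),
    night_shift_band = c("1", "2", "3-4", "5-8", ">=9"),
    off_days_band = c("1-2", "2-3"),
    marital_status = c("Married", "Unmarried", "Divorced", "Other"),
    children_band = c("0", "1", "2", ">=3")
  )
}

# legal numeric range per item column
item_range <- function(col) {
  if (col %in% c(psqi_cols(), phq9_cols(), phq9_reverse_col())) c(0L, 3L)
  else if (col %in% nsbq_cols()) c(1L, 5L)
  else stop("not an item column: ", col)
}

item_cols <- function() c(psqi_cols(), phq9_cols(), phq9_reverse_col(), nsbq_cols())
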