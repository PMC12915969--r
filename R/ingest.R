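#' Read a participant survey table
#'
#' Reads one row per respondent from a CSV or XLSX file (first sheet), binds
#' the file's headers to the pipeline's canonical column names through a
#' schema map, and coerces item columns to integers. Cells outside an item's
#' legal range (0-3 for PSQI components, PHQ-9 items and the reverse check;
#' 1-5 for NSBQ items) are set to missing with one warning summarising the
#' count. Row order is preserved.
#'
#' @param path Path to the survey file.
#' @param dialect `"csv"` or `"xlsx"`. Defaults to the file extension.
#' @param schema_map Named character vector mapping canonical column names
#'   (names) to the file's column headers (values). Canonical names not in
#'   the map are assumed to appear verbatim in the file. A YAML or JSON file
#'   path may be given instead; it must parse to a flat name-to-name map.
#' @return A tibble with canonical columns: `participant_id`, `source` (if
#'   present), the twelve covariates, `PSQI_C1..C7`, `D_1..D_9`, `D_1R`,
#'   `NSBQ_1..12`, and `qc_flag` (filled with `"none"` when absent).
#' @export
read_survey_table <- function(path, dialect = c("auto", "csv", "xlsx"),
                              schema_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("survey file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  raw <- switch(dialect,
    csv = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading xlsx requires the 'readxl' package")
      readxl::read_excel(path, sheet = 1)
    }
  )
  if (nrow(raw) == 0L) stop("survey file is empty: ", path)
  schema_map <- load_schema_map(schema_map)

  # resolve every canonical column against the file header
  mandatory <- c(covariate_cols(), item_cols())
  optional <- c("participant_id", "source", "qc_flag")
  resolve <- function(canon) if (canon %in% names(schema_map)) schema_map[[canon]] else canon
  missing_cols <- mandatory[!vapply(mandatory, resolve, "") %in% names(raw)]
  if (length(missing_cols) > 0L) {
    stop("schema error: unmapped mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- tibble::tibble(.rows = nrow(raw))
  for (canon in c(optional, mandatory)) {
    src <- resolve(canon)
    if (src %in% names(raw)) out[[canon]] <- raw[[src]]
  }
  if (is.null(out[["participant_id"]])) out$participant_id <- sprintf("P%05d", seq_len(nrow(out)))
  out$participant_id <- as.character(out$participant_id)
  if (is.null(out[["qc_flag"]])) out$qc_flag <- "none"

  # coerce items, voiding out-of-range cells
  n_bad <- 0L
  for (col in item_cols()) {
    v <- suppressWarnings(as.integer(out[[col]]))
    rng <- item_range(col)
    bad <- !is.na(v) & (v < rng[1] | v > rng[2])
    n_bad <- n_bad + sum(bad)
    v[bad] <- NA_integer_
    out[[col]] <- v
  }
  if (n_bad > 0L) {
    warning(sprintf("%d out-of-range item cell(s) set to missing", n_bad))
  }
  levs <- covariate_levels()
  for (cv in covariate_cols()) {
    out[[cv]] <- as.character(out[[cv]])
    unknown <- setdiff(unique(out[[cv]][!is.na(out[[cv]])]), levs[[cv]])
    if (length(unknown) > 0L) {
      warning(sprintf("covariate '%s': unknown label(s) %s set to missing",
                      cv, paste(unknown, collapse = ", ")))
      out[[cv]][out[[cv]] %in% unknown] <- NA_character_
    }
    out[[cv]] <- factor(out[[cv]], levels = levs[[cv]])
  }
  out
}

load_schema_map <- function(schema_map) {
  if (is.null(schema_map)) return(character())
  if (is.character(schema_map) && length(schema_map) == 1L && file.exists(schema_map)) {
    schema_map <- if (grepl("\\.json$", schema_map)) {
      unlist(jsonlite::read_json(schema_map))
    } else {
      unlist(yaml::read_yaml(schema_map))
    }
  }
  stopifnot(is.character(schema_map))
  if (length(schema_map) > 0L && is.null(names(schema_map)))
    stop("schema_map must be named (canonical = file column)")
  schema_map
}

#' Write a cohort table to CSV
#'
#' @param records Cohort tibble as produced by [read_survey_table()] or
#'   [generate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}
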