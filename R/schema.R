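# Patient-level survey record schema: one row per patient per monthly
# point-prevalence survey, demographics plus the four harm findings.

#' Closed vocabularies of the survey record
#'
#' Returns the permitted levels for every categorical field of the
#' patient-level survey record. The survey is collected by forced-choice
#' drop-downs, so unknown tokens are rejected at parse time rather than
#' coerced to missing.
#'
#' @return Named list of character vectors, one per categorical column.
#' @export
#' @examples
#' survey_levels()$setting
survey_levels <- function() {
  list(
    setting = c("hospital_ward", "community_hospital", "hospice",
                "nursing_home", "own_home", "residential_care_home", "other"),
    age_band = c("under_18", "18_70", "over_70"),
    gender = c("male", "female"),
    pu_category = c("2", "3", "4"),
    pu_origin = c("old", "new"),
    fall_severity = c("none", "low", "moderate", "severe", "death"),
    uti_onset = c("old", "new"),
    vte_risk_assessed = c("yes", "no", "not_applicable"),
    vte_at_risk = c("yes", "no", "not_applicable"),
    vte_prophylaxis = c("appropriate", "not_given", "not_applicable"),
    vte_onset = c("old", "new"),
    vte_type = c("dvt", "pe", "other")
  )
}

# column -> "date", "character", "logical" or name of a survey_levels() entry
survey_column_spec <- function() {
  c(survey_date = "date", org_id = "character", ward_id = "character",
    setting = "setting", age_band = "age_band", gender = "gender",
    specialty = "character",
    pu_present = "logical", pu_category = "pu_category",
    pu_origin = "pu_origin",
    fall_72h = "logical", fall_severity = "fall_severity",
    catheter_72h = "logical", uti_treated = "logical",
    uti_onset = "uti_onset",
    vte_risk_assessed = "vte_risk_assessed", vte_at_risk = "vte_at_risk",
    vte_prophylaxis = "vte_prophylaxis", vte_treated = "logical",
    vte_onset = "vte_onset", vte_type = "vte_type")
}

#' Canonical column names of a survey table
#'
#' @return Character vector of the column names, in canonical order.
#' @export
survey_columns <- function() names(survey_column_spec())

# columns that must never be missing (detail fields may be NA when the
# governing flag is negative; those pairings are checked by validate_surveys)
required_survey_columns <- function() {
  c("survey_date", "org_id", "ward_id", "setting", "age_band", "gender",
    "pu_present", "fall_72h", "catheter_72h", "uti_treated",
    "vte_risk_assessed", "vte_at_risk", "vte_prophylaxis", "vte_treated")
}

parse_survey_logical <- function(x, column) {
  if (is.logical(x)) return(x)
  x <- as.character(x)
  out <- rep(NA, length(x))
  out[x %in% "yes"] <- TRUE
  out[x %in% "no"] <- FALSE
  bad <- !is.na(x) & !x %in% c("yes", "no")
  if (any(bad)) {
    stop(sprintf("column '%s': invalid boolean token(s): %s (expected yes/no)",
                 column, paste(unique(x[bad]), collapse = ", ")),
         call. = FALSE)
  }
  out
}

parse_survey_factor <- function(x, column, levels) {
  x <- as.character(x)
  bad <- !is.na(x) & !x %in% levels
  if (any(bad)) {
    stop(sprintf("column '%s': unknown token(s): %s (allowed: %s)",
                 column, paste(unique(x[bad]), collapse = ", "),
                 paste(levels, collapse = ", ")),
         call. = FALSE)
  }
  factor(x, levels = levels)
}

#' Coerce a data frame to a validated survey table
#'
#' Checks the header against the canonical schema, parses booleans
#' (`"yes"`/`"no"`), dates (ISO-8601) and the closed categorical
#' vocabularies, and rejects unknown tokens or missing values in
#' always-present fields. Cross-field consistency (e.g. ulcer detail
#' without an ulcer) is *not* checked here; see [validate_surveys()].
#'
#' @param data A data frame with the columns of [survey_columns()]; extra
#'   columns are an error, categorical columns may be character or factor.
#' @return A tibble with one row per patient record, typed columns, and the
#'   input's `provenance` attribute preserved.
#' @seealso [read_surveys()], [validate_surveys()]
#' @export
as_survey <- function(data) {
  spec <- survey_column_spec()
  missing_cols <- setdiff(names(spec), names(data))
  if (length(missing_cols) > 0) {
    stop("malformed survey header; missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(data), names(spec))
  if (length(extra) > 0) {
    stop("unknown survey column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  lv <- survey_levels()
  out <- tibble::as_tibble(data)[, names(spec)]
  for (col in names(spec)) {
    kind <- spec[[col]]
    out[[col]] <- switch(
      kind,
      date = as.Date(out[[col]]),
      character = as.character(out[[col]]),
      logical = parse_survey_logical(out[[col]], col),
      parse_survey_factor(out[[col]], col, lv[[kind]])
    )
  }
  req <- required_survey_columns()
  for (col in req) {
    if (anyNA(out[[col]])) {
      stop(sprintf("column '%s' must be present for every record (%d missing)",
                   col, sum(is.na(out[[col]]))), call. = FALSE)
    }
  }
  attr(out, "provenance") <- attr(data, "provenance", exact = TRUE)
  out
}

#' Read patient-level survey records from CSV
#'
#' Reads an RFC-4180 CSV (UTF-8, header row) with one row per patient
#' record, booleans spelled `yes`/`no`, categorical fields in their
#' lower-snake tokens, and blank cells for detail fields that do not apply.
#'
#' @param file Path to a survey CSV.
#' @return A validated survey tibble with `provenance` set to `file`.
#' @export
read_surveys <- function(file) {
  if (!file.exists(file)) stop("cannot read file: ", file, call. = FALSE)
  raw <- readr::read_csv(file, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  out <- as_survey(raw)
  attr(out, "provenance") <- as.character(file)
  out
}

#' Write patient-level survey records to CSV
#'
#' Serialises booleans as `yes`/`no`, dates as ISO-8601 and missing detail
#' fields as empty cells, so that [read_surveys()] round-trips the table
#' field-for-field.
#'
#' @param data A survey tibble (see [as_survey()]).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_surveys <- function(data, file) {
  data <- as_survey(data)
  out <- data
  for (col in names(out)) {
    if (is.logical(out[[col]])) {
      out[[col]] <- ifelse(out[[col]], "yes", "no")
    } else if (is.factor(out[[col]])) {
      out[[col]] <- as.character(out[[col]])
    }
  }
  readr::write_csv(out, file, na = "", progress = FALSE)
  invisible(file)
}

#' Merge-lineage provenance of a survey batch
#'
#' @param x A survey tibble.
#' @return Character vector of source tags (file paths or batch labels)
#'   accumulated through [read_surveys()] and [merge_surveys()].
#' @export
provenance <- function(x) {
  p <- attr(x, "provenance", exact = TRUE)
  if (is.null(p)) character(0) else p
}

#' @rdname provenance
#' @param value Replacement character vector of source tags.
#' @export
`provenance<-` <- function(x, value) {
  attr(x, "provenance") <- as.character(value)
  x
}
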