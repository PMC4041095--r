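# Cross-field validation rules mirroring the instrument's cross-validation
# checks. Enum membership and always-present fields are enforced earlier, at
# parse time (as_survey); these rules catch inconsistent field pairings.

validation_rules <- function() {
  list(
    list(rule_id = "pu_detail_missing", field = "pu_category",
         message = "pressure ulcer recorded but category or origin missing",
         test = function(d) d$pu_present &
           (is.na(d$pu_category) | is.na(d$pu_origin))),
    list(rule_id = "pu_detail_requires_ulcer", field = "pu_present",
         message = "pressure ulcer category/origin recorded without an ulcer",
         test = function(d) !d$pu_present &
           (!is.na(d$pu_category) | !is.na(d$pu_origin))),
    list(rule_id = "fall_severity_missing", field = "fall_severity",
         message = "fall recorded but severity missing",
         test = function(d) d$fall_72h & is.na(d$fall_severity)),
    list(rule_id = "fall_severity_requires_fall", field = "fall_severity",
         message = "fall severity recorded without a fall",
         test = function(d) !d$fall_72h & !is.na(d$fall_severity)),
    list(rule_id = "uti_onset_missing", field = "uti_onset",
         message = "treated UTI recorded but onset missing",
         test = function(d) d$uti_treated & is.na(d$uti_onset)),
    list(rule_id = "uti_onset_requires_uti", field = "uti_onset",
         message = "UTI onset recorded without treated UTI",
         test = function(d) !d$uti_treated & !is.na(d$uti_onset)),
    list(rule_id = "prophylaxis_requires_at_risk", field = "vte_prophylaxis",
         message = "VTE prophylaxis recorded for a patient not at risk",
         test = function(d) d$vte_prophylaxis != "not_applicable" &
           d$vte_at_risk != "yes"),
    list(rule_id = "vte_detail_missing", field = "vte_onset",
         message = "treated VTE recorded but onset or type missing",
         test = function(d) d$vte_treated &
           (is.na(d$vte_onset) | is.na(d$vte_type))),
    list(rule_id = "vte_detail_requires_treatment", field = "vte_treated",
         message = "VTE onset/type recorded without treatment",
         test = function(d) !d$vte_treated &
           (!is.na(d$vte_onset) | !is.na(d$vte_type)))
  )
}

#' Validate survey records against the cross-field rules
#'
#' Applies the instrument's cross-validation checks to every record:
#' pressure-ulcer category/origin must be present exactly when an ulcer is
#' recorded, fall severity exactly when a fall is recorded, UTI onset
#' exactly when a treated UTI is recorded, VTE onset/type exactly when a
#' treated VTE is recorded, and prophylaxis may only be recorded for
#' patients assessed as at risk. Violations are reported, never raised.
#'
#' @param data A survey tibble (see [as_survey()]).
#' @return A tibble with one row per violation and columns `record` (row
#'   index), `field`, `rule_id`, `severity` (`"error"`), and `message`,
#'   ordered by record then rule id. Zero rows means the batch passes every
#'   rule.
#' @export
#' @examples
#' batch <- generate_cohort(scenario_config(
#'   n_orgs = 1, wards_per_org = 1, patients_per_ward_month = 20, seed = 1))
#' validate_surveys(batch)
validate_surveys <- function(data) {
  data <- as_survey(data)
  empty <- tibble::tibble(record = integer(), field = character(),
                          rule_id = character(), severity = character(),
                          message = character())
  if (nrow(data) == 0) return(empty)
  issues <- purrr::map(validation_rules(), function(rule) {
    hit <- which(rule$test(data))
    if (length(hit) == 0) return(NULL)
    tibble::tibble(record = hit, field = rule$field, rule_id = rule$rule_id,
                   severity = "error", message = rule$message)
  })
  out <- dplyr::bind_rows(empty, issues)
  dplyr::arrange(out, .data$record, .data$rule_id)
}
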