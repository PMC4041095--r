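# The published measure catalogue and the harm-free-care composite.
# Each measure is a numerator rule and a denominator rule over the survey
# table; all proportions carry exact binomial confidence intervals.

measure_ids <- function() {
  c("P1", "P2", "P3", "F1", "F2", "C1", "C2", "C3", "UTI_NO_CATH",
    "V1", "V2", "V3", "V4")
}

# severity values counting as harm from a fall ("none" = fell without harm)
fall_harm_levels <- function() c("low", "moderate", "severe", "death")

#' The published measure catalogue
#'
#' @return A tibble listing every measure id in dashboard order with its
#'   numerator and denominator description. `HARM_FREE` (the composite) is
#'   included last.
#' @export
measure_catalogue <- function() {
  tibble::tribble(
    ~measure_id, ~numerator_rule, ~denominator_rule,
    "P1", "old pressure ulcer (present on admission or within 72 h)",
    "all patients",
    "P2", "new pressure ulcer (developed after 72 h)", "all patients",
    "P3", "any pressure ulcer, old or new", "all patients",
    "F1", "fall in a care setting in the last 72 h", "all patients",
    "F2", "fall with harm (severity at least low)", "all patients",
    "C1", "urethral catheter in situ or removed in last 72 h", "all patients",
    "C2", "catheter and treated UTI (any onset)", "all patients",
    "C3", "catheter and treated new UTI", "all patients",
    "UTI_NO_CATH", "treated UTI without a catheter", "all patients",
    "V1", "VTE risk assessment done",
    "patients for whom assessment is applicable",
    "V2", "appropriate VTE prophylaxis", "patients assessed as at risk",
    "V3", "treated new VTE", "all patients",
    "V4", "treated old VTE", "all patients",
    "HARM_FREE", "none of the four configured harms", "all patients"
  )
}

# numerator / denominator logical vectors for one measure
measure_flags <- function(data, measure_id, category = NULL, severity = NULL) {
  all_pat <- rep(TRUE, nrow(data))
  if (!is.null(category) && !measure_id %in% c("P1", "P2", "P3")) {
    stop("category filter only applies to pressure-ulcer measures",
         call. = FALSE)
  }
  if (!is.null(severity) && !measure_id %in% c("F1", "F2")) {
    stop("severity filter only applies to fall measures", call. = FALSE)
  }
  pu_cat_ok <- if (is.null(category)) all_pat else {
    category <- as.character(category)
    if (!category %in% survey_levels()$pu_category) {
      stop("category must be one of 2, 3, 4", call. = FALSE)
    }
    !is.na(data$pu_category) & data$pu_category == category
  }
  sev_ok <- if (is.null(severity)) all_pat else {
    if (!severity %in% survey_levels()$fall_severity) {
      stop("severity must be one of ",
           paste(survey_levels()$fall_severity, collapse = ", "),
           call. = FALSE)
    }
    !is.na(data$fall_severity) & data$fall_severity == severity
  }
  fall_harm <- data$fall_72h & !is.na(data$fall_severity) &
    data$fall_severity %in% fall_harm_levels()
  switch(
    measure_id,
    P1 = list(num = data$pu_present & data$pu_origin %in% "old" & pu_cat_ok,
              den = all_pat),
    P2 = list(num = data$pu_present & data$pu_origin %in% "new" & pu_cat_ok,
              den = all_pat),
    P3 = list(num = data$pu_present & pu_cat_ok, den = all_pat),
    F1 = list(num = data$fall_72h & sev_ok, den = all_pat),
    F2 = list(num = fall_harm & sev_ok, den = all_pat),
    C1 = list(num = data$catheter_72h, den = all_pat),
    C2 = list(num = data$catheter_72h & data$uti_treated, den = all_pat),
    C3 = list(num = data$catheter_72h & data$uti_treated &
                data$uti_onset %in% "new", den = all_pat),
    UTI_NO_CATH = list(num = data$uti_treated & !data$catheter_72h,
                       den = all_pat),
    V1 = list(num = data$vte_risk_assessed == "yes",
              den = data$vte_risk_assessed != "not_applicable"),
    V2 = list(num = data$vte_at_risk == "yes" &
                data$vte_prophylaxis == "appropriate",
              den = data$vte_at_risk == "yes"),
    V3 = list(num = data$vte_treated & data$vte_onset %in% "new",
              den = all_pat),
    V4 = list(num = data$vte_treated & data$vte_onset %in% "old",
              den = all_pat),
    stop("unknown measure id: ", measure_id, call. = FALSE)
  )
}

measure_result <- function(measure_id, numerator, denominator,
                           ci_level = 0.95) {
  k <- max(length(measure_id), length(numerator))
  measure_id <- rep_len(measure_id, k)
  numerator <- rep_len(as.integer(numerator), k)
  denominator <- rep_len(as.integer(denominator), k)
  prop <- ifelse(denominator > 0, numerator / denominator, NA_real_)
  ci <- tibble::tibble(low = rep(NA_real_, k), high = rep(NA_real_, k))
  pos <- denominator > 0
  if (any(pos)) {
    ci[pos, ] <- exact_binomial_ci(numerator[pos], denominator[pos],
                                   level = ci_level)
  }
  tibble::tibble(measure_id = measure_id, numerator = numerator,
                 denominator = denominator, proportion = prop,
                 ci_low = ci$low, ci_high = ci$high, ci_level = ci_level)
}

#' Compute one published measure on a survey batch
#'
#' Numerator and denominator rules follow the final operational
#' definitions: P1/P2/P3 pressure ulcers (old / new / any, worst ulcer
#' only), F1/F2 falls (any / with harm), C1/C2/C3 catheter and
#' catheter-with-UTI, `UTI_NO_CATH` treated UTI without a catheter, and
#' the VTE cascade V1 (risk assessment done, among patients for whom it is
#' applicable), V2 (appropriate prophylaxis, among patients assessed as at
#' risk), V3/V4 (treated new / old VTE). All other denominators are all
#' surveyed patients; C2/C3 in particular are proportions of *all*
#' patients, not of catheterised patients.
#'
#' @param data A survey tibble.
#' @param measure_id One of `P1`, `P2`, `P3`, `F1`, `F2`, `C1`, `C2`, `C3`,
#'   `UTI_NO_CATH`, `V1`, `V2`, `V3`, `V4`.
#' @param category Optional pressure-ulcer category view (`2`, `3` or `4`);
#'   restricts the numerator of P1/P2/P3 to that category of worst ulcer.
#' @param severity Optional fall-severity view for F1/F2.
#' @param ci_level Confidence level for the exact binomial interval.
#' @return A one-row tibble: `measure_id`, `numerator`, `denominator`,
#'   `proportion`, `ci_low`, `ci_high`, `ci_level`. With an empty batch the
#'   denominator is 0 and proportion and interval are `NA`.
#' @export
#' @examples
#' batch <- generate_cohort(scenario_config(seed = 42))
#' compute_measure(batch, "P3")
#' compute_measure(batch, "P3", category = 2)
compute_measure <- function(data, measure_id, category = NULL,
                            severity = NULL, ci_level = 0.95) {
  data <- as_survey(data)
  if (length(measure_id) != 1 || !measure_id %in% measure_ids()) {
    stop("unknown measure id: ", paste(measure_id, collapse = ", "),
         call. = FALSE)
  }
  fl <- measure_flags(data, measure_id, category = category,
                      severity = severity)
  measure_result(measure_id, sum(fl$num & fl$den), sum(fl$den),
                 ci_level = ci_level)
}

#' Configure the harm-free-care composite
#'
#' "Harm-free care" is the absence of all four surveyed harms in the same
#' patient on the survey day. The survey publishes only that principle, so
#' which variant of each harm counts is configurable. The defaults count:
#' any pressure ulcer (old or new), a fall *with* harm, a catheter with a
#' treated UTI of any onset, and a treated *new* VTE.
#'
#' @param pu `"any"`, `"new_only"` or `"none"`.
#' @param fall `"fall_with_harm"` or `"any_fall"`.
#' @param uti `"catheter_and_any_uti"` or `"catheter_and_new_uti"`.
#' @param vte `"new_only"` or `"any"`.
#' @return An object of class `harm_definition`.
#' @export
harm_definition <- function(pu = c("any", "new_only", "none"),
                            fall = c("fall_with_harm", "any_fall"),
                            uti = c("catheter_and_any_uti",
                                    "catheter_and_new_uti"),
                            vte = c("new_only", "any")) {
  out <- list(pu = match.arg(pu), fall = match.arg(fall),
              uti = match.arg(uti), vte = match.arg(vte))
  structure(out, class = "harm_definition")
}

#' @export
print.harm_definition <- function(x, ...) {
  cat("Harm-free composite definition:\n")
  cat("  pressure ulcer:", x$pu, "\n  fall:", x$fall,
      "\n  catheter/UTI:", x$uti, "\n  VTE:", x$vte, "\n")
  invisible(x)
}

# per-patient logical: does any configured harm apply?
any_harm_flag <- function(data, definition) {
  pu <- switch(definition$pu,
               any = data$pu_present,
               new_only = data$pu_present & data$pu_origin %in% "new",
               none = rep(FALSE, nrow(data)))
  fall <- switch(definition$fall,
                 any_fall = data$fall_72h,
                 fall_with_harm = data$fall_72h &
                   data$fall_severity %in% fall_harm_levels())
  uti <- switch(definition$uti,
                catheter_and_any_uti = data$catheter_72h & data$uti_treated,
                catheter_and_new_uti = data$catheter_72h & data$uti_treated &
                  data$uti_onset %in% "new")
  vte <- switch(definition$vte,
                any = data$vte_treated,
                new_only = data$vte_treated & data$vte_onset %in% "new")
  pu | fall | uti | vte
}

#' Harm-free care proportion
#'
#' Proportion of surveyed patients with none of the four configured harms
#' on the survey day (see [harm_definition()]).
#'
#' @inheritParams compute_measure
#' @param definition A [harm_definition()].
#' @return A one-row measure tibble with `measure_id = "HARM_FREE"`.
#' @export
#' @examples
#' batch <- generate_cohort(scenario_config(seed = 42))
#' harm_free_proportion(batch)
harm_free_proportion <- function(data, definition = harm_definition(),
                                 ci_level = 0.95) {
  data <- as_survey(data)
  stopifnot(inherits(definition, "harm_definition"))
  measure_result("HARM_FREE", sum(!any_harm_flag(data, definition)),
                 nrow(data), ci_level = ci_level)
}

#' Summary dashboard: every catalogue measure plus the composite
#'
#' @inheritParams harm_free_proportion
#' @return A 14-row tibble: the 13 catalogue measures in fixed order
#'   (P1-P3, F1-F2, C1-C3, UTI_NO_CATH, V1-V4) followed by `HARM_FREE`.
#' @export
#' @examples
#' batch <- generate_cohort(scenario_config(seed = 42))
#' dashboard(batch)
dashboard <- function(data, definition = harm_definition(),
                      ci_level = 0.95) {
  data <- as_survey(data)
  rows <- purrr::map(measure_ids(), function(id) {
    fl <- measure_flags(data, id)
    c(num = sum(fl$num & fl$den), den = sum(fl$den))
  })
  counts <- do.call(rbind, rows)
  out <- measure_result(measure_ids(), counts[, "num"], counts[, "den"],
                        ci_level = ci_level)
  dplyr::bind_rows(out, harm_free_proportion(data, definition, ci_level))
}
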