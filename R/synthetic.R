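# Synthetic multi-organization survey cohorts. Defaults emulate the
# national pilot: setting mix 90% hospital / 3% own home / 2% nursing home /
# 5% other, and harm prevalences set to the published national proportions.
# Harms are drawn independently per patient (no comorbidity structure),
# which is what makes the harm-free product check an exact oracle; an
# optional shared-frailty multiplier is available to induce positive
# correlation between harms.

prob_params <- function() {
  c("p_pu_old", "p_pu_new", "p_fall", "p_fall_harm_given_fall", "p_cath",
    "p_uti_given_cath", "p_uti_new_given_uti", "p_uti_no_cath", "p_vte_na",
    "p_vte_assessed", "p_at_risk", "p_prophylaxis_given_risk",
    "p_vte_treated", "p_vte_new_given_treated")
}

mix_params <- function() {
  c("setting_mix", "pu_category_mix", "fall_harm_severity_mix",
    "vte_type_mix")
}

#' Configure a synthetic survey scenario
#'
#' Defines a multi-organization, multi-month cohort: the sampling frame
#' (organizations x wards x patients per ward-month x months), the setting
#' mix, and the harm-generating probabilities. The defaults are the
#' national-pilot conditions: the published setting mix (90% hospital
#' ward, 3% own home, 2% nursing home, 5% other) and the published
#' national prevalences — 6.5% old / 1.02% new pressure ulcers, 3.22%
#' falls (39.1% of them with harm), 16.73% catheters, a treated-UTI rate
#' among all patients of 2.03% given a catheter (so
#' `p_uti_given_cath = 0.0203 / 0.1673`), 69.27% VTE risk assessment,
#' 55.16% prophylaxis among at-risk patients, and 3.64% treated VTE of
#' which 41.5% new.
#'
#' @param n_orgs,wards_per_org,patients_per_ward_month Sampling frame
#'   counts (per month).
#' @param months Number of consecutive monthly surveys.
#' @param seed Integer seed; the scenario is seeded once and generation is
#'   fully reproducible.
#' @param start_month First survey month, `"YYYY-MM"`; the survey day is
#'   the 15th of each month.
#' @param setting_mix Named fractions over care settings, summing to 1.
#' @param p_pu_old,p_pu_new Marginal probabilities of an old / new worst
#'   pressure ulcer (mutually exclusive; their sum is the any-PU rate).
#' @param pu_category_mix Category (2/3/4) distribution of the worst ulcer.
#' @param p_fall Probability of a fall in a care setting in the last 72 h.
#' @param p_fall_harm_given_fall Probability a fall caused harm (severity
#'   at least low).
#' @param fall_harm_severity_mix Distribution of low/moderate/severe/death
#'   given a harmful fall.
#' @param p_cath Probability of a urethral catheter (in situ or removed in
#'   the last 72 h).
#' @param p_uti_given_cath Probability of a treated UTI given a catheter.
#' @param p_uti_new_given_uti Probability a treated UTI is new.
#' @param p_uti_no_cath Probability of a treated UTI given no catheter.
#' @param p_vte_na Probability the whole VTE cascade is not applicable
#'   (e.g. end-of-life care).
#' @param p_vte_assessed Probability of a documented risk assessment,
#'   among applicable patients.
#' @param p_at_risk Probability a risk-assessed patient is at risk.
#' @param p_prophylaxis_given_risk Probability an at-risk patient receives
#'   appropriate prophylaxis.
#' @param p_vte_treated Probability of anticoagulant treatment for a
#'   documented VTE.
#' @param p_vte_new_given_treated Probability a treated VTE is new.
#' @param vte_type_mix Distribution of dvt/pe/other given treatment.
#' @param frailty_sd Standard deviation (log scale) of an optional
#'   per-patient lognormal frailty multiplier applied to the four
#'   top-level harm probabilities; 0 (default) keeps harms independent.
#' @param step_change Optional `list(month =, effects =)` where `effects`
#'   is a named vector of multiplicative factors on probability
#'   parameters, applied from `month` onward by [generate_series()].
#' @return An object of class `scenario_config`.
#' @export
#' @examples
#' cfg <- scenario_config(n_orgs = 2, seed = 1)
#' cfg$p_cath
scenario_config <- function(n_orgs = 10,
                            wards_per_org = 5,
                            patients_per_ward_month = 25,
                            months = 6,
                            seed = 2012L,
                            start_month = "2012-07",
                            setting_mix = c(hospital_ward = 0.90,
                                            own_home = 0.03,
                                            nursing_home = 0.02,
                                            other = 0.05),
                            p_pu_old = 0.065,
                            p_pu_new = 0.0102,
                            pu_category_mix = c(`2` = 0.60, `3` = 0.30,
                                                `4` = 0.10),
                            p_fall = 0.0322,
                            p_fall_harm_given_fall = 0.0126 / 0.0322,
                            fall_harm_severity_mix = c(low = 0.75,
                                                       moderate = 0.18,
                                                       severe = 0.05,
                                                       death = 0.02),
                            p_cath = 0.1673,
                            p_uti_given_cath = 0.0203 / 0.1673,
                            p_uti_new_given_uti = 0.0104 / 0.0203,
                            p_uti_no_cath = 0.03,
                            p_vte_na = 0.05,
                            p_vte_assessed = 0.6927,
                            p_at_risk = 0.55,
                            p_prophylaxis_given_risk = 0.5516,
                            p_vte_treated = 0.0364,
                            p_vte_new_given_treated = 0.0151 / 0.0364,
                            vte_type_mix = c(dvt = 0.55, pe = 0.35,
                                             other = 0.10),
                            frailty_sd = 0,
                            step_change = NULL) {
  cfg <- as.list(environment())
  counts <- c("n_orgs", "wards_per_org", "patients_per_ward_month", "months")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (length(v) != 1 || !is.finite(v) || v < 1 || v != round(v)) {
      stop(nm, " must be a positive integer", call. = FALSE)
    }
    cfg[[nm]] <- as.integer(v)
  }
  cfg$seed <- as.integer(seed)
  for (nm in prob_params()) {
    v <- cfg[[nm]]
    if (length(v) != 1 || !is.finite(v) || v < 0 || v > 1) {
      stop(nm, " must be a probability in [0, 1]", call. = FALSE)
    }
  }
  if (p_pu_old + p_pu_new > 1) {
    stop("p_pu_old + p_pu_new must not exceed 1", call. = FALSE)
  }
  lv <- survey_levels()
  mix_domains <- list(setting_mix = lv$setting,
                      pu_category_mix = lv$pu_category,
                      fall_harm_severity_mix = setdiff(lv$fall_severity,
                                                       "none"),
                      vte_type_mix = lv$vte_type)
  for (nm in mix_params()) {
    m <- cfg[[nm]]
    if (is.null(names(m)) || !all(names(m) %in% mix_domains[[nm]])) {
      stop(nm, " must be named with levels among: ",
           paste(mix_domains[[nm]], collapse = ", "), call. = FALSE)
    }
    if (any(m < 0) || abs(sum(m) - 1) > 1e-9) {
      stop(nm, " must be non-negative and sum to 1 (tolerance 1e-9)",
           call. = FALSE)
    }
  }
  if (frailty_sd < 0) stop("frailty_sd must be non-negative", call. = FALSE)
  if (!is.null(step_change)) {
    if (!is.list(step_change) ||
        !all(c("month", "effects") %in% names(step_change))) {
      stop("step_change must be list(month =, effects =)", call. = FALSE)
    }
    if (step_change$month < 1 || step_change$month > cfg$months) {
      stop("step_change month outside 1..months", call. = FALSE)
    }
    bad <- setdiff(names(step_change$effects), prob_params())
    if (length(bad) > 0) {
      stop("step_change effects name unknown parameter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(cfg, class = "scenario_config")
}

#' The national-pilot scenario preset
#'
#' [scenario_config()] with its published-national defaults, exposed under
#' its own name so scripts can request the preset explicitly; any argument
#' can still be overridden.
#'
#' @param ... Overrides passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
national_pilot_scenario <- function(...) scenario_config(...)

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(paste0("synthetic survey scenario: %d orgs x %d wards x %d ",
                     "patients/ward-month, %d month(s), seed %d\n"),
              x$n_orgs, x$wards_per_org, x$patients_per_ward_month,
              x$months, x$seed))
  invisible(x)
}

sample_level <- function(n, mix, levels) {
  full <- setNames(rep(0, length(levels)), levels)
  full[names(mix)] <- mix
  factor(sample(levels, n, replace = TRUE, prob = full), levels = levels)
}

# one month's cohort; assumes the RNG stream is already positioned
gen_month_records <- function(cfg, month_index, effects = NULL) {
  p <- cfg
  if (!is.null(effects)) {
    for (nm in names(effects)) {
      p[[nm]] <- min(1, max(0, p[[nm]] * effects[[nm]]))
    }
  }
  n <- cfg$n_orgs * cfg$wards_per_org * cfg$patients_per_ward_month
  lv <- survey_levels()
  first <- as.Date(paste0(cfg$start_month, "-01"))
  month0 <- seq(first, by = "month", length.out = month_index)[month_index]
  survey_day <- month0 + 14  # mid-month census day

  org <- rep(sprintf("org%02d", seq_len(cfg$n_orgs)),
             each = cfg$wards_per_org * cfg$patients_per_ward_month)
  ward <- rep(rep(sprintf("ward%d", seq_len(cfg$wards_per_org)),
                  each = cfg$patients_per_ward_month), cfg$n_orgs)

  frail <- if (cfg$frailty_sd > 0) {
    exp(stats::rnorm(n, -cfg$frailty_sd^2 / 2, cfg$frailty_sd))
  } else rep(1, n)
  padj <- function(prob) pmin(1, prob * frail)

  pu_any <- stats::runif(n) < padj(p$p_pu_old + p$p_pu_new)
  pu_origin <- factor(rep(NA_character_, n), levels = lv$pu_origin)
  pu_category <- factor(rep(NA_character_, n), levels = lv$pu_category)
  k <- sum(pu_any)
  if (k > 0) {
    share_old <- p$p_pu_old / (p$p_pu_old + p$p_pu_new)
    pu_origin[pu_any] <- sample(lv$pu_origin, k, replace = TRUE,
                                prob = c(share_old, 1 - share_old))
    pu_category[pu_any] <- sample_level(k, p$pu_category_mix,
                                        lv$pu_category)[seq_len(k)]
  }

  fell <- stats::runif(n) < padj(p$p_fall)
  fall_severity <- factor(rep(NA_character_, n), levels = lv$fall_severity)
  k <- sum(fell)
  if (k > 0) {
    harm <- stats::runif(k) < p$p_fall_harm_given_fall
    sev <- rep("none", k)
    if (any(harm)) {
      sev[harm] <- as.character(sample_level(sum(harm),
                                             p$fall_harm_severity_mix,
                                             setdiff(lv$fall_severity,
                                                     "none")))
    }
    fall_severity[fell] <- sev
  }

  cath <- stats::runif(n) < padj(p$p_cath)
  uti <- stats::runif(n) < ifelse(cath, p$p_uti_given_cath, p$p_uti_no_cath)
  uti_onset <- factor(rep(NA_character_, n), levels = lv$uti_onset)
  k <- sum(uti)
  if (k > 0) {
    uti_onset[uti] <- sample(lv$uti_onset, k, replace = TRUE,
                             prob = c(1 - p$p_uti_new_given_uti,
                                      p$p_uti_new_given_uti))
  }

  vte_na <- stats::runif(n) < p$p_vte_na
  assessed <- !vte_na & (stats::runif(n) < p$p_vte_assessed)
  risk_assessed <- factor(ifelse(vte_na, "not_applicable",
                                 ifelse(assessed, "yes", "no")),
                          levels = lv$vte_risk_assessed)
  at_risk_yes <- assessed & (stats::runif(n) < p$p_at_risk)
  at_risk <- factor(ifelse(assessed, ifelse(at_risk_yes, "yes", "no"),
                           "not_applicable"),
                    levels = lv$vte_at_risk)
  proph_ok <- at_risk_yes & (stats::runif(n) < p$p_prophylaxis_given_risk)
  prophylaxis <- factor(ifelse(at_risk_yes,
                               ifelse(proph_ok, "appropriate", "not_given"),
                               "not_applicable"),
                        levels = lv$vte_prophylaxis)
  treated <- stats::runif(n) < padj(p$p_vte_treated)
  vte_onset <- factor(rep(NA_character_, n), levels = lv$vte_onset)
  vte_type <- factor(rep(NA_character_, n), levels = lv$vte_type)
  k <- sum(treated)
  if (k > 0) {
    vte_onset[treated] <- sample(lv$vte_onset, k, replace = TRUE,
                                 prob = c(1 - p$p_vte_new_given_treated,
                                          p$p_vte_new_given_treated))
    vte_type[treated] <- sample_level(k, p$vte_type_mix, lv$vte_type)
  }

  tibble::tibble(
    survey_date = rep(survey_day, n),
    org_id = org,
    ward_id = ward,
    setting = sample_level(n, cfg$setting_mix, lv$setting),
    age_band = factor(sample(lv$age_band, n, replace = TRUE),
                      levels = lv$age_band),
    gender = factor(sample(lv$gender, n, replace = TRUE),
                    levels = lv$gender),
    specialty = sample(c("medicine", "surgery", "elderly_care", "community"),
                       n, replace = TRUE),
    pu_present = pu_any, pu_category = pu_category, pu_origin = pu_origin,
    fall_72h = fell, fall_severity = fall_severity,
    catheter_72h = cath, uti_treated = uti, uti_onset = uti_onset,
    vte_risk_assessed = risk_assessed, vte_at_risk = at_risk,
    vte_prophylaxis = prophylaxis, vte_treated = treated,
    vte_onset = vte_onset, vte_type = vte_type
  )
}

with_scenario_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate one month's synthetic survey cohort
#'
#' Draws a single monthly point-prevalence cohort from a scenario: every
#' ward surveys its configured number of patients on the mid-month survey
#' day, settings follow the configured mix, and harms are drawn
#' independently per patient from the configured probabilities. Output is
#' reproducible given the scenario seed and always passes
#' [validate_surveys()] with zero issues.
#'
#' @param config A [scenario_config()].
#' @return A survey tibble with
#'   `n_orgs * wards_per_org * patients_per_ward_month` records.
#' @export
#' @examples
#' batch <- generate_cohort(scenario_config(n_orgs = 2, seed = 9))
#' nrow(batch)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  out <- with_scenario_seed(config$seed,
                            gen_month_records(config, month_index = 1))
  out <- as_survey(out)
  provenance(out) <- sprintf("synthetic:seed=%d:month=1", config$seed)
  out
}

#' Generate a monthly series of synthetic cohorts
#'
#' Draws `config$months` independent monthly cohorts from one random
#' stream seeded once. When `config$step_change` is set, the named
#' probability parameters are multiplied by their effects (clamped to
#' [0, 1]) from the given month onward — a simple model of an
#' improvement intervention.
#'
#' @param config A [scenario_config()].
#' @return A list of survey tibbles, one per month, named `"YYYY-MM"`.
#' @export
#' @examples
#' series <- generate_series(scenario_config(n_orgs = 1, months = 3,
#'                                           seed = 4))
#' names(series)
generate_series <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  first <- as.Date(paste0(config$start_month, "-01"))
  months <- format(seq(first, by = "month", length.out = config$months),
                   "%Y-%m")
  out <- with_scenario_seed(config$seed, {
    purrr::map(seq_len(config$months), function(m) {
      effects <- NULL
      sc <- config$step_change
      if (!is.null(sc) && m >= sc$month) effects <- sc$effects
      gen_month_records(config, month_index = m, effects = effects)
    })
  })
  out <- purrr::map(out, as_survey)
  for (m in seq_along(out)) {
    provenance(out[[m]]) <- sprintf("synthetic:seed=%d:month=%d",
                                    config$seed, m)
  }
  setNames(out, months)
}

#' Read a scenario from a YAML or JSON file
#'
#' @param file Path to a scenario file; keys are [scenario_config()]
#'   arguments (mixes as named maps, `step_change` as
#'   `{month:, effects: {param: factor}}`).
#' @return A `scenario_config`.
#' @export
read_scenario <- function(file) {
  if (!file.exists(file)) stop("cannot read file: ", file, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", file, ignore.case = TRUE)) {
    yaml::read_yaml(file)
  } else {
    jsonlite::read_json(file, simplifyVector = TRUE)
  }
  for (nm in mix_params()) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  if (!is.null(raw$step_change)) {
    raw$step_change$effects <- unlist(raw$step_change$effects)
  }
  do.call(scenario_config, raw)
}
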