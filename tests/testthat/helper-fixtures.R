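# Fixtures built in code: a fully-specified clean record with overridable
# fields, and small hand-constructed batches for the worked examples.

make_record <- function(...) {
  rec <- tibble::tibble(
    survey_date = as.Date("2012-07-15"),
    org_id = "orgA", ward_id = "ward1",
    setting = "hospital_ward", age_band = "18_70", gender = "female",
    specialty = "medicine",
    pu_present = FALSE, pu_category = NA_character_,
    pu_origin = NA_character_,
    fall_72h = FALSE, fall_severity = NA_character_,
    catheter_72h = FALSE, uti_treated = FALSE, uti_onset = NA_character_,
    vte_risk_assessed = "yes", vte_at_risk = "no",
    vte_prophylaxis = "not_applicable", vte_treated = FALSE,
    vte_onset = NA_character_, vte_type = NA_character_
  )
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

make_batch <- function(...) {
  as_survey(dplyr::bind_rows(...))
}

# worked 10-patient batch: 1 old PU (cat 2), 1 new PU (cat 3), 8 clean
worked_pu_batch <- function() {
  make_batch(
    make_record(pu_present = TRUE, pu_category = "2", pu_origin = "old"),
    make_record(pu_present = TRUE, pu_category = "3", pu_origin = "new"),
    purrr::map(1:8, ~ make_record())
  )
}

# random scenario with probabilities drawn uniformly at modest levels,
# used by the measures-algebra property suite
random_scenario <- function(seed) {
  set.seed(seed)
  scenario_config(
    n_orgs = 1, wards_per_org = 1, patients_per_ward_month = 30,
    months = 1, seed = seed,
    p_pu_old = runif(1, 0, 0.2), p_pu_new = runif(1, 0, 0.2),
    p_fall = runif(1, 0, 0.3), p_fall_harm_given_fall = runif(1),
    p_cath = runif(1, 0, 0.4), p_uti_given_cath = runif(1),
    p_uti_new_given_uti = runif(1), p_uti_no_cath = runif(1, 0, 0.2),
    p_vte_na = runif(1, 0, 0.2), p_vte_assessed = runif(1),
    p_at_risk = runif(1), p_prophylaxis_given_risk = runif(1),
    p_vte_treated = runif(1, 0, 0.3), p_vte_new_given_treated = runif(1)
  )
}
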