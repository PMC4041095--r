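# Measure catalogue: worked counts, denominator conventions, filters,
# harm-free composite and its algebraic relations to the components.

test_that("pressure-ulcer measures follow the worst-ulcer old/new split", {
  b <- worked_pu_batch()
  expect_equal(compute_measure(b, "P1")$proportion, 0.1)
  expect_equal(compute_measure(b, "P2")$proportion, 0.1)
  p3 <- compute_measure(b, "P3")
  expect_equal(p3$proportion, 0.2)
  expect_equal(p3$numerator, 2L)
  expect_equal(p3$denominator, 10L)
  # category views partition the numerator
  expect_equal(compute_measure(b, "P3", category = 2)$numerator, 1L)
  expect_equal(compute_measure(b, "P3", category = 3)$numerator, 1L)
  expect_equal(compute_measure(b, "P3", category = 4)$numerator, 0L)
  expect_error(compute_measure(b, "C1", category = 2), "category filter")
  expect_error(compute_measure(b, "XX"), "unknown measure")
})

test_that("catheter/UTI measures use the all-patients denominator", {
  b <- make_batch(
    make_record(catheter_72h = TRUE, uti_treated = TRUE, uti_onset = "new"),
    make_record(catheter_72h = TRUE),
    purrr::map(1:7, ~ make_record()),
    make_record(uti_treated = TRUE, uti_onset = "old")  # UTI, no catheter
  )
  expect_equal(compute_measure(b, "C1")$proportion, 0.2)
  expect_equal(compute_measure(b, "C2")$proportion, 0.1)
  expect_equal(compute_measure(b, "C3")$proportion, 0.1)
  expect_equal(compute_measure(b, "UTI_NO_CATH")$proportion, 0.1)
  expect_true(compute_measure(b, "C3")$numerator <=
                compute_measure(b, "C2")$numerator)
})

test_that("VTE cascade denominators exclude not-applicable and non-at-risk patients", {
  b <- make_batch(
    make_record(vte_risk_assessed = "yes", vte_at_risk = "yes",
                vte_prophylaxis = "appropriate"),
    make_record(vte_risk_assessed = "yes", vte_at_risk = "yes",
                vte_prophylaxis = "not_given"),
    make_record(vte_risk_assessed = "no", vte_at_risk = "not_applicable"),
    make_record(vte_risk_assessed = "not_applicable",
                vte_at_risk = "not_applicable"),
    make_record(vte_treated = TRUE, vte_onset = "new", vte_type = "pe"),
    make_record(vte_treated = TRUE, vte_onset = "old", vte_type = "dvt")
  )
  v1 <- compute_measure(b, "V1")
  expect_equal(v1$denominator, 5L)  # one not_applicable excluded
  expect_equal(v1$numerator, 4L)
  v2 <- compute_measure(b, "V2")
  expect_equal(v2$denominator, 2L)  # at-risk patients only
  expect_equal(v2$proportion, 0.5)
  expect_equal(compute_measure(b, "V3")$numerator +
                 compute_measure(b, "V4")$numerator,
               sum(b$vte_treated))
})

test_that("harm-free composite counts the configured absence of all four harms", {
  clean <- make_batch(purrr::map(1:5, ~ make_record()))
  expect_equal(harm_free_proportion(clean)$proportion, 1)

  one_each <- make_batch(
    make_record(pu_present = TRUE, pu_category = "2", pu_origin = "old"),
    make_record(fall_72h = TRUE, fall_severity = "moderate"),
    make_record(catheter_72h = TRUE, uti_treated = TRUE,
                uti_onset = "old"),
    make_record(vte_treated = TRUE, vte_onset = "new", vte_type = "dvt")
  )
  expect_equal(harm_free_proportion(one_each)$proportion, 0)

  # non-default definitions change what counts as harm
  fell_no_harm <- make_batch(make_record(fall_72h = TRUE,
                                         fall_severity = "none"))
  expect_equal(harm_free_proportion(fell_no_harm)$proportion, 1)
  expect_equal(harm_free_proportion(
    fell_no_harm, harm_definition(fall = "any_fall"))$proportion, 0)
  old_vte <- make_batch(make_record(vte_treated = TRUE, vte_onset = "old",
                                    vte_type = "other"))
  expect_equal(harm_free_proportion(old_vte)$proportion, 1)
  expect_equal(harm_free_proportion(
    old_vte, harm_definition(vte = "any"))$proportion, 0)
})

test_that("dashboard returns the full catalogue in fixed order with denominator-0 handling", {
  d <- dashboard(worked_pu_batch())
  expect_equal(nrow(d), 14)
  expect_equal(d$measure_id, c("P1", "P2", "P3", "F1", "F2", "C1", "C2",
                               "C3", "UTI_NO_CATH", "V1", "V2", "V3", "V4",
                               "HARM_FREE"))
  expect_equal(d$proportion[d$measure_id == "P3"], 0.2)

  empty <- dashboard(make_record()[0, ])
  expect_equal(nrow(empty), 14)
  expect_true(all(empty$denominator == 0))
  expect_true(all(is.na(empty$proportion)))
  expect_true(all(is.na(empty$ci_low)))
})

test_that("harm-free proportion matches the independence product on synthetic batches", {
  q <- c(pu = 0.08, fall_harm = 0.05, cath_uti = 0.03, new_vte = 0.02)
  cfg <- scenario_config(
    n_orgs = 1, wards_per_org = 1, patients_per_ward_month = 40000,
    seed = 7, p_pu_old = 0.05, p_pu_new = 0.03,
    p_fall = 0.05, p_fall_harm_given_fall = 1,     # every fall harmful
    p_cath = 1, p_uti_given_cath = 0.03,           # cath+UTI rate 0.03
    p_uti_no_cath = 0, p_vte_treated = 0.02, p_vte_new_given_treated = 1)
  hf <- harm_free_proportion(generate_cohort(cfg))
  expected <- prod(1 - q)
  se <- sqrt(expected * (1 - expected) / hf$denominator)
  expect_lt(abs(hf$proportion - expected), 3 * se)
})

test_that("every reported proportion lies inside its own confidence interval", {
  for (seed in c(11, 12, 13)) {
    d <- dashboard(generate_cohort(random_scenario(seed)))
    pos <- d$denominator > 0
    expect_true(all(d$ci_low[pos] <= d$proportion[pos] + 1e-12))
    expect_true(all(d$proportion[pos] <= d$ci_high[pos] + 1e-12))
  }
})
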