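# Synthetic cohort generator: determinism, structural validity, mix and
# conditional-probability recovery, step changes.

test_that("generated cohorts are valid, reproducible and byte-identical on disk", {
  cfg <- scenario_config(n_orgs = 2, wards_per_org = 2,
                         patients_per_ward_month = 50, seed = 123)
  b1 <- generate_cohort(cfg)
  expect_equal(nrow(b1), 2 * 2 * 50)
  expect_equal(nrow(validate_surveys(b1)), 0)

  b2 <- generate_cohort(cfg)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_surveys(b1, f1); write_surveys(generate_cohort(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))

  # generation does not disturb the caller's random stream
  set.seed(99); before <- runif(5)
  set.seed(99); invisible(generate_cohort(cfg)); after <- runif(5)
  expect_identical(before, after)
})

test_that("all-zero harm probabilities give perfect harm-free care", {
  cfg <- scenario_config(n_orgs = 1, patients_per_ward_month = 30,
                         seed = 5, p_pu_old = 0, p_pu_new = 0, p_fall = 0,
                         p_cath = 0, p_uti_given_cath = 0,
                         p_uti_no_cath = 0, p_vte_treated = 0)
  b <- generate_cohort(cfg)
  expect_equal(harm_free_proportion(b)$proportion, 1)
  expect_equal(harm_free_proportion(
    b, harm_definition(fall = "any_fall", vte = "any"))$proportion, 1)
})

test_that("setting mix and harm conditionals are recovered at scale", {
  cfg <- scenario_config(n_orgs = 1, wards_per_org = 1,
                         patients_per_ward_month = 100000, seed = 31)
  b <- generate_cohort(cfg)
  obs <- table(b$setting)[names(cfg$setting_mix)]
  gof <- chisq_gof(as.integer(obs), unname(cfg$setting_mix))
  expect_gt(gof$p_value, 0.001)

  # uti-with-catheter frequency ~ p_cath * p_uti_given_cath
  target <- cfg$p_cath * cfg$p_uti_given_cath
  c2 <- compute_measure(b, "C2")
  se <- sqrt(target * (1 - target) / nrow(b))
  expect_lt(abs(c2$proportion - target), 3 * se)
})

test_that("invalid scenario parameters are rejected", {
  expect_error(scenario_config(p_cath = 1.2), "probability")
  expect_error(scenario_config(p_pu_old = 0.7, p_pu_new = 0.5),
               "must not exceed 1")
  expect_error(scenario_config(setting_mix = c(hospital_ward = 0.5)),
               "sum to 1")
  expect_error(scenario_config(n_orgs = 0), "positive integer")
  expect_error(scenario_config(months = 3,
                               step_change = list(month = 9,
                                                  effects = c(p_cath = 0.5))),
               "outside")
  expect_error(scenario_config(step_change = list(month = 2,
                                                  effects = c(p_zzz = 0.5))),
               "unknown parameter")
})

test_that("a one-month series equals the single-cohort draw", {
  cfg <- scenario_config(n_orgs = 1, months = 1, seed = 77)
  s <- generate_series(cfg)
  expect_length(s, 1)
  expect_identical(as.data.frame(s[[1]]),
                   as.data.frame(generate_cohort(cfg)))
  expect_equal(names(s), "2012-07")
})

test_that("a step change halving catheter use shows up in the pooled series", {
  cfg <- scenario_config(n_orgs = 2, wards_per_org = 5,
                         patients_per_ward_month = 25, months = 12,
                         seed = 19,
                         step_change = list(month = 7,
                                            effects = c(p_cath = 0.5)))
  s <- generate_series(cfg)
  expect_length(s, 12)
  pre <- merge_surveys(s[1:6])
  post <- merge_surveys(s[7:12])
  c1_pre <- compute_measure(pre, "C1")
  c1_post <- compute_measure(post, "C1")
  # designed power: ~0.167 vs ~0.084 at 1500 per phase is > 7 SE apart
  expect_lt(c1_post$proportion, c1_pre$proportion)
  tst <- two_proportion_test(c1_pre$numerator, c1_pre$denominator,
                             c1_post$numerator, c1_post$denominator)
  expect_lt(tst$p_value, 0.001)

  # a no-op step leaves the draw unchanged
  cfg_null <- scenario_config(n_orgs = 1, months = 3, seed = 21,
                              step_change = list(month = 2,
                                                 effects = c(p_cath = 1)))
  cfg_free <- scenario_config(n_orgs = 1, months = 3, seed = 21)
  expect_identical(purrr::map(generate_series(cfg_null), as.data.frame),
                   purrr::map(generate_series(cfg_free), as.data.frame))
})

test_that("the bundled national-pilot scenario file matches the preset", {
  f <- system.file("extdata", "national_pilot.yaml", package = "harmsurvey")
  expect_true(nzchar(f))
  cfg <- read_scenario(f)
  preset <- national_pilot_scenario()
  for (nm in c("p_cath", "p_pu_old", "p_vte_assessed", "months", "seed")) {
    expect_equal(cfg[[nm]], preset[[nm]], tolerance = 1e-12)
  }
  expect_equal(unname(cfg$setting_mix), unname(preset$setting_mix))
})

test_that("the frailty hook induces positive association between harms", {
  base <- scenario_config(n_orgs = 1, wards_per_org = 1,
                          patients_per_ward_month = 60000, seed = 47,
                          p_pu_old = 0.1, p_pu_new = 0.05, p_fall = 0.15,
                          frailty_sd = 1)
  b <- generate_cohort(base)
  # P(PU and fall) > P(PU) P(fall) under shared frailty
  joint <- mean(b$pu_present & b$fall_72h)
  indep <- mean(b$pu_present) * mean(b$fall_72h)
  expect_gt(joint, indep)
})
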