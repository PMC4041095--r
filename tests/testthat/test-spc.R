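# p-charts, run-chart rules and the sample-size planners.

series_tbl <- function(num, den) {
  tibble::tibble(period = sprintf("2012-%02d", seq_along(num)),
                 numerator = num, denominator = den)
}

test_that("p-chart centre line pools the baseline and limits use each point's n", {
  ch <- pchart(series_tbl(rep(5, 6), rep(10, 6)))
  expect_equal(ch$centre_line, 0.5)
  expect_true(all(tidy(ch)$signal == "none"))

  # at n = 9 and p-bar = 0.5 the lower limit is exactly zero
  ch9 <- pchart(series_tbl(c(5, 4), c(10, 9)), baseline = 1)
  expect_equal(tidy(ch9)$lcl[2], 0)
  expect_gt(tidy(ch9)$ucl[2], tidy(ch9)$ucl[1])  # smaller n, wider limits

  # rare harm at n = 100: limits clamp to zero below the planning threshold
  ch_rare <- pchart(series_tbl(round(0.0212 * 500), 500),
                    baseline = 1)
  expect_true(100 < min_n_for_positive_lcl(0.0212))
  p_bar <- ch_rare$centre_line
  lcl100 <- max(0, p_bar - 3 * sqrt(p_bar * (1 - p_bar) / 100))
  expect_equal(lcl100, 0)

  expect_error(pchart(series_tbl(0, 0)), "denominators are zero")
  expect_error(pchart(series_tbl(c(5, 5), c(10, 10))[c(2, 1), ]),
               "strictly increasing")
})

test_that("a point below a positive LCL signals, one at the limit does not", {
  # baseline p-bar = 0.5 from five 50/100 months, then a 0/10 month
  ch <- pchart(series_tbl(c(rep(50, 5), 0), c(rep(100, 5), 10)),
               baseline = 1:5)
  td <- tidy(ch)
  lcl10 <- 0.5 - 3 * sqrt(0.25 / 10)  # direct limit computation
  expect_gt(lcl10, 0)
  expect_equal(td$lcl[6], lcl10)
  expect_equal(td$signal[6], "below_lcl")
  expect_equal(glance(ch)$n_signals, 1)

  # clamped limits never leave [0, 1]
  for (p in c(0.01, 0.3, 0.97)) {
    td <- tidy(pchart(series_tbl(round(p * 1000), 1000), baseline = 1))
    expect_true(all(td$lcl >= 0) && all(td$ucl <= 1))
  }
})

test_that("run-chart shift and trend rules follow the 6-point and 5-point conventions", {
  alternating <- series_tbl(rep(c(3, 7), 5), rep(10, 10))
  expect_equal(nrow(runchart(alternating)$signals), 0)

  # 13 points, median exactly 0.5: six below, then six above with one
  # on-median point in the middle of the run (skipped, not a break)
  shifted <- series_tbl(c(1, 2, 1, 2, 1, 2, 8, 5, 9, 8, 9, 8, 9),
                        rep(10, 13))
  rc <- runchart(shifted)
  expect_equal(rc$median, 0.5)
  expect_setequal(rc$signals$type, c("shift_above", "shift_below"))
  expect_equal(rc$signals$length, c(6L, 6L))

  trending <- series_tbl(c(5, 4, 1, 2, 3, 4, 5), rep(10, 7))
  rc <- runchart(trending)
  expect_equal(rc$signals$type, "trend_up")
  expect_equal(rc$signals$length, 5L)
  expect_equal(runchart(series_tbl(7:3, rep(10, 5)))$signals$type,
               "trend_down")
  # four ascending points are not enough
  expect_equal(nrow(runchart(series_tbl(c(5, 1, 2, 3, 4, 1),
                                        rep(10, 6)))$signals), 0)

  expect_error(runchart(series_tbl(5, 10)), "at least 2")
})

test_that("minimum n for three expected events reproduces the published planning row", {
  averages <- c(new_pu = 0.0212, old_pu = 0.0616, all_pu = 0.0828,
                falls = 0.0347, falls_harm = 0.0143, catheters = 0.1764,
                cath_uti = 0.025, new_vte = 0.0198, old_vte = 0.0232)
  published_n_chart <- c(142, 49, 37, 87, 210, 18, 120, 152, 130)
  expect_equal(purrr::map_int(averages, min_n_for_expected_events),
               setNames(published_n_chart, names(averages)))
  expect_equal(min_n_for_expected_events(0.5), 6L)
  expect_equal(min_n_for_expected_events(0.5, k = 4.5), 9L)
  expect_error(min_n_for_expected_events(0), "between 0 and 1")
  expect_error(min_n_for_expected_events(1), "between 0 and 1")
})

test_that("minimum n for a positive LCL matches brute-force limit signs and is monotone", {
  expect_equal(min_n_for_positive_lcl(0.1764), 43L)
  expect_equal(min_n_for_positive_lcl(0.0616), 138L)
  expect_equal(min_n_for_positive_lcl(0.5), 10L)  # LCL(9) is exactly 0

  lcl <- function(p, n) p - 3 * sqrt(p * (1 - p) / n)
  for (p in c(0.003, 0.04, 0.1764, 0.33, 0.5)) {
    m <- min_n_for_positive_lcl(p)
    expect_gt(lcl(p, m), 0)
    if (m > 1) expect_lte(lcl(p, m - 1), 0)
  }
  grid <- seq(0.005, 0.5, length.out = 100)
  ns <- purrr::map_int(grid, min_n_for_positive_lcl)
  expect_true(all(diff(ns) <= 0))  # rarer harms need more patients
  expect_error(min_n_for_positive_lcl(-0.1), "between 0 and 1")
})

test_that("the sample-size plan recommends the maximum over selected measures", {
  averages <- c(new_pu = 0.0212, old_pu = 0.0616, all_pu = 0.0828,
                falls = 0.0347, falls_harm = 0.0143, catheters = 0.1764,
                cath_uti = 0.025, new_vte = 0.0198, old_vte = 0.0232)
  plan <- sample_size_plan(averages, criterion = "chart")
  expect_equal(plan$n_chart, c(142L, 49L, 37L, 87L, 210L, 18L, 120L, 152L,
                               130L))
  expect_equal(attr(plan, "recommended"), 210L)
  expect_equal(glance(plan)$recommended, 210L)

  single <- sample_size_plan(c(falls_harm = 0.0143))
  expect_equal(attr(single, "recommended"),
               min_n_for_positive_lcl(0.0143))

  two <- sample_size_plan(c(a = 0.5, b = 0.0212), criterion = "lcl")
  expect_equal(attr(two, "recommended"), min_n_for_positive_lcl(0.0212))

  sel <- sample_size_plan(averages, selected = c("catheters", "all_pu"))
  expect_equal(attr(sel, "recommended"), 100L)  # all-PU dominates catheters

  expect_error(sample_size_plan(averages, selected = character(0)),
               "at least one")
  expect_error(sample_size_plan(averages, selected = "nope"), "absent")
})
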