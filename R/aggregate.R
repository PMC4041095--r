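# Merge survey batches and roll monthly summaries up the
# ward -> organization -> region -> national hierarchy.

#' Merge survey batches
#'
#' Record multiset union of any number of survey batches, with provenance
#' concatenated in input order and records sorted deterministically by
#' organization, ward, date, then input order. No deduplication is
#' performed: the survey carries no patient identifiers, so
#' duplicate-looking rows are legal.
#'
#' @param ... Survey tibbles, or a single list of survey tibbles.
#' @return One merged survey tibble; `provenance()` holds all input tags.
#' @export
#' @examples
#' a <- generate_cohort(scenario_config(n_orgs = 1, seed = 1))
#' b <- generate_cohort(scenario_config(n_orgs = 1, seed = 2))
#' nrow(merge_surveys(a, b)) == nrow(a) + nrow(b)
merge_surveys <- function(...) {
  batches <- list(...)
  if (length(batches) == 1 && is.list(batches[[1]]) &&
      !is.data.frame(batches[[1]])) {
    batches <- batches[[1]]
  }
  if (length(batches) == 0) {
    out <- as_survey(empty_survey())
    provenance(out) <- character(0)
    return(out)
  }
  batches <- purrr::map(batches, as_survey)
  tags <- purrr::imap(batches, function(b, i) {
    p <- provenance(b)
    if (length(p) == 0) sprintf("batch_%d", i) else p
  })
  out <- dplyr::bind_rows(batches)
  ord <- order(out$org_id, out$ward_id, out$survey_date)  # stable sort
  out <- out[ord, ]
  out <- as_survey(out)
  provenance(out) <- unlist(tags)
  out
}

empty_survey <- function() {
  spec <- survey_column_spec()
  lv <- survey_levels()
  cols <- purrr::imap(spec, function(kind, col) {
    switch(kind,
           date = as.Date(character(0)),
           character = character(0),
           logical = logical(0),
           factor(character(0), levels = lv[[kind]]))
  })
  tibble::as_tibble(cols)
}

rollup_group_id <- function(data, level, region_map = NULL) {
  switch(
    level,
    ward = paste(data$org_id, data$ward_id, sep = "/"),
    organization = data$org_id,
    region = {
      if (is.null(region_map)) {
        stop("region rollup requires a region_map (org_id -> region)",
             call. = FALSE)
      }
      region_map <- unlist(region_map)
      unmapped <- setdiff(unique(data$org_id), names(region_map))
      if (length(unmapped) > 0) {
        stop("org id(s) missing from region_map: ",
             paste(sort(unmapped), collapse = ", "), call. = FALSE)
      }
      unname(region_map[data$org_id])
    },
    national = rep("national", nrow(data)),
    stop("level must be ward, organization, region or national",
         call. = FALSE)
  )
}

#' Roll up monthly measure summaries at a hierarchy level
#'
#' Computes the full [dashboard()] for every (group, month) cell at the
#' requested level. Numerators and denominators are conserved up the
#' hierarchy: for any measure and month, ward summaries within an
#' organization sum to the organization summary, and so on up to national.
#'
#' @param data A survey tibble.
#' @param level `"ward"`, `"organization"`, `"region"` or `"national"`.
#' @param region_map Named vector or list mapping `org_id` to region name;
#'   required when `level = "region"`. Organizations without a mapping are
#'   an error (listed in the message).
#' @param definition A [harm_definition()] for the composite.
#' @param ci_level Confidence level for the intervals.
#' @return A tibble with one row per group, month and measure: `level`,
#'   `period` (`"YYYY-MM"`), `group_id`, then the measure columns of
#'   [dashboard()]. Empty input gives a zero-row tibble.
#' @export
#' @examples
#' batch <- generate_cohort(scenario_config(n_orgs = 2, seed = 7))
#' rollup(batch, "organization")
rollup <- function(data, level = c("ward", "organization", "region",
                                   "national"),
                   region_map = NULL, definition = harm_definition(),
                   ci_level = 0.95) {
  level <- match.arg(level)
  data <- as_survey(data)
  if (nrow(data) == 0) {
    return(tibble::tibble(level = character(), period = character(),
                          group_id = character(),
                          measure_result("P1", 0, 0)[0, ]))
  }
  data$.group <- rollup_group_id(data, level, region_map)
  data$.period <- format(data$survey_date, "%Y-%m")
  cells <- split(seq_len(nrow(data)),
                 list(data$.group, data$.period), drop = TRUE)
  cells <- cells[order(names(cells))]
  out <- purrr::imap(cells, function(idx, key) {
    sub <- data[idx, setdiff(names(data), c(".group", ".period"))]
    res <- dashboard(as_survey(sub), definition, ci_level)
    dplyr::bind_cols(tibble::tibble(level = level,
                                    period = data$.period[idx[1]],
                                    group_id = data$.group[idx[1]]),
                     res)
  })
  dplyr::bind_rows(out)
}

#' Compare group summaries against a reference
#'
#' For every group, month and measure: the group proportion with its exact
#' interval, the reference proportion, their difference, a flag raised when
#' the reference proportion lies outside the group's interval, and the
#' uncorrected chi-square p-value of [two_proportion_test()]. The output
#' carries a `"note"` attribute stating it is not for ranking: point
#' prevalences from small monthly samples are too noisy to order teams.
#'
#' @param summaries A [rollup()] tibble for the groups to compare.
#' @param reference A [rollup()] tibble for a single reference group (for
#'   instance the national rollup of the same period).
#' @return A tibble with one row per group, period and measure. Empty
#'   `summaries` give a zero-row tibble.
#' @export
comparison_report <- function(summaries, reference) {
  empty <- tibble::tibble(group_id = character(), period = character(),
                          measure_id = character(), numerator = integer(),
                          denominator = integer(), proportion = double(),
                          ci_low = double(), ci_high = double(),
                          ref_proportion = double(), difference = double(),
                          flag = logical(), p_value = double())
  attr(empty, "note") <-
    "Comparisons between organizations or teams are not for ranking."
  if (is.null(summaries) || nrow(summaries) == 0) return(empty)
  need <- c("group_id", "period", "measure_id", "numerator", "denominator",
            "proportion", "ci_low", "ci_high")
  stopifnot(all(need %in% names(summaries)), all(need %in% names(reference)))
  if (length(unique(reference$group_id)) != 1) {
    stop("reference must contain a single group", call. = FALSE)
  }
  if (!setequal(unique(summaries$measure_id), unique(reference$measure_id))) {
    stop("summaries and reference must share the same measure catalogue",
         call. = FALSE)
  }
  ref <- reference[, c("measure_id", "numerator", "denominator",
                       "proportion")]
  names(ref) <- c("measure_id", "ref_numerator", "ref_denominator",
                  "ref_proportion")
  out <- dplyr::inner_join(summaries, ref, by = "measure_id")
  out$difference <- out$proportion - out$ref_proportion
  out$flag <- !is.na(out$proportion) & !is.na(out$ref_proportion) &
    (out$ref_proportion < out$ci_low | out$ref_proportion > out$ci_high)
  out$p_value <- purrr::pmap_dbl(
    out[, c("numerator", "denominator", "ref_numerator", "ref_denominator")],
    function(numerator, denominator, ref_numerator, ref_denominator) {
      if (denominator == 0 || ref_denominator == 0) return(NA_real_)
      two_proportion_test(numerator, denominator,
                          ref_numerator, ref_denominator)$p_value
    })
  out <- out[, c("group_id", "period", "measure_id", "numerator",
                 "denominator", "proportion", "ci_low", "ci_high",
                 "ref_proportion", "difference", "flag", "p_value")]
  attr(out, "note") <-
    "Comparisons between organizations or teams are not for ranking."
  out
}
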