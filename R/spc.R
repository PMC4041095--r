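# Statistical process control for monthly proportion series: run charts,
# variable-denominator 3-sigma p-charts, and the attribute-chart sample-size
# planners used to decide how many patients to survey each month.

check_series <- function(series) {
  need <- c("period", "numerator", "denominator")
  if (!is.data.frame(series) || !all(need %in% names(series))) {
    stop("series must be a data frame with columns period, numerator, ",
         "denominator", call. = FALSE)
  }
  series <- tibble::as_tibble(series)[, need]
  if (nrow(series) < 1) stop("series needs at least one point", call. = FALSE)
  if (any(series$denominator < 0) || any(series$numerator < 0) ||
      any(series$numerator > series$denominator)) {
    stop("each point must satisfy 0 <= numerator <= denominator",
         call. = FALSE)
  }
  per <- series$period
  ord <- if (inherits(per, "Date")) as.numeric(per) else as.character(per)
  if (is.unsorted(ord, strictly = TRUE)) {
    stop("periods must be strictly increasing", call. = FALSE)
  }
  series
}

#' Variable-denominator p-chart for a monthly proportion series
#'
#' Shewhart proportions chart with 3-sigma limits recomputed from each
#' point's own denominator. The centre line is the pooled proportion over
#' the baseline points, `p-bar = sum(num) / sum(den)`; per-point limits are
#' `p-bar +/- sigma * sqrt(p-bar * (1 - p-bar) / n_i)`, clamped to [0, 1].
#' A point is a signal when its proportion falls strictly outside its own
#' limits.
#'
#' @param series Data frame with columns `period` (strictly increasing),
#'   `numerator` and `denominator`.
#' @param baseline Integer indices of the points that define the centre
#'   line; defaults to all points. Useful to freeze limits on a
#'   pre-intervention phase.
#' @param sigma Width of the limits in standard deviations (default 3).
#' @return An object of class `pchart`; see [tidy.pchart()],
#'   [glance.pchart()], [autoplot.pchart()].
#' @export
#' @examples
#' series <- tibble::tibble(period = sprintf("2012-%02d", 1:6),
#'                          numerator = c(5, 4, 6, 5, 3, 7),
#'                          denominator = rep(30, 6))
#' pchart(series)
pchart <- function(series, baseline = NULL, sigma = 3) {
  series <- check_series(series)
  if (all(series$denominator == 0)) {
    stop("all denominators are zero; no chart can be drawn", call. = FALSE)
  }
  if (is.null(baseline)) baseline <- seq_len(nrow(series))
  if (any(baseline < 1 | baseline > nrow(series))) {
    stop("baseline indices out of range", call. = FALSE)
  }
  den_b <- sum(series$denominator[baseline])
  if (den_b == 0) stop("baseline has zero total denominator", call. = FALSE)
  p_bar <- sum(series$numerator[baseline]) / den_b
  n <- series$denominator
  half <- ifelse(n > 0, sigma * sqrt(p_bar * (1 - p_bar) / n), NA_real_)
  dat <- series
  dat$proportion <- ifelse(n > 0, series$numerator / n, NA_real_)
  dat$centre <- p_bar
  dat$lcl <- pmax(0, p_bar - half)
  dat$ucl <- pmin(1, p_bar + half)
  dat$signal <- dplyr::case_when(
    is.na(dat$proportion) ~ NA_character_,
    dat$proportion > dat$ucl ~ "above_ucl",
    dat$proportion < dat$lcl ~ "below_lcl",
    TRUE ~ "none"
  )
  structure(list(data = dat, centre_line = p_bar, baseline = baseline,
                 sigma = sigma),
            class = "pchart")
}

#' @export
print.pchart <- function(x, ...) {
  sig <- sum(x$data$signal %in% c("above_ucl", "below_lcl"))
  cat(sprintf("p-chart: %d points, centre line %.4f, %d signal(s)\n",
              nrow(x$data), x$centre_line, sig))
  print(x$data, ...)
  invisible(x)
}

#' @describeIn pchart Per-point chart table: `period`, `numerator`,
#'   `denominator`, `proportion`, `centre`, `lcl`, `ucl`, `signal`.
#' @param x A `pchart` object.
#' @param ... Unused.
#' @method tidy pchart
#' @export
tidy.pchart <- function(x, ...) x$data

#' @describeIn pchart One-row summary: centre line, number of points,
#'   number of signals.
#' @method glance pchart
#' @export
glance.pchart <- function(x, ...) {
  tibble::tibble(
    centre_line = x$centre_line,
    n_points = nrow(x$data),
    n_signals = sum(x$data$signal %in% c("above_ucl", "below_lcl")),
    sigma = x$sigma
  )
}

#' @describeIn pchart ggplot of the chart: proportion series, centre line,
#'   stepped control limits, signals highlighted.
#' @param object A `pchart` object.
#' @method autoplot pchart
#' @export
autoplot.pchart <- function(object, ...) {
  dat <- object$data
  dat$x <- seq_len(nrow(dat))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$proportion)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$ucl), linetype = "dashed",
                       colour = "grey40") +
    ggplot2::geom_step(ggplot2::aes(y = .data$lcl), linetype = "dashed",
                       colour = "grey40") +
    ggplot2::geom_hline(yintercept = object$centre_line,
                        colour = "grey20") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$signal != "none"),
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "red")) +
    ggplot2::scale_x_continuous(breaks = dat$x,
                                labels = as.character(dat$period)) +
    ggplot2::labs(x = "period", y = "proportion",
                  title = sprintf("p-chart (centre %.3f, %d-sigma limits)",
                                  object$centre_line, object$sigma)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

# maximal runs of TRUE in a logical vector -> list of index vectors
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  purrr::map2(starts[r$values], ends[r$values], seq)
}

#' Run chart with shift and trend rules
#'
#' Plots proportions against a median centre line and applies the two
#' standard quality-improvement rules: a *shift* is six or more consecutive
#' points on the same side of the median (points exactly on the median are
#' skipped, not counted for either side); a *trend* is five or more
#' consecutive strictly ascending or strictly descending points.
#'
#' @inheritParams pchart
#' @return An object of class `runchart` with elements `data` (per-point
#'   tibble), `median` and `signals` (one row per maximal qualifying run:
#'   `period` of the run's last point, `type`, `length`).
#' @export
#' @examples
#' series <- tibble::tibble(period = sprintf("2012-%02d", 1:8),
#'                          numerator = 1:8, denominator = rep(20, 8))
#' runchart(series)$signals
runchart <- function(series) {
  series <- check_series(series)
  if (nrow(series) < 2) {
    stop("a run chart needs at least 2 points", call. = FALSE)
  }
  if (any(series$denominator == 0)) {
    stop("run chart points need positive denominators", call. = FALSE)
  }
  p <- series$numerator / series$denominator
  med <- median(p)
  dat <- series
  dat$proportion <- p
  dat$median <- med

  signals <- tibble::tibble(period = series$period[0], type = character(),
                            length = integer())
  # shift: >= 6 consecutive off-median points on one side, medians skipped
  off <- p != med
  side <- ifelse(p > med, "above", "below")
  idx <- which(off)
  if (length(idx) > 0) {
    for (run in runs_of(c(side[idx] == "above"))) {
      if (length(run) >= 6) {
        signals <- dplyr::bind_rows(signals, tibble::tibble(
          period = series$period[idx[run[length(run)]]],
          type = "shift_above", length = length(run)))
      }
    }
    for (run in runs_of(c(side[idx] == "below"))) {
      if (length(run) >= 6) {
        signals <- dplyr::bind_rows(signals, tibble::tibble(
          period = series$period[idx[run[length(run)]]],
          type = "shift_below", length = length(run)))
      }
    }
  }
  # trend: >= 5 consecutive strictly monotone points (4 strict steps)
  if (length(p) >= 5) {
    dif <- diff(p)
    for (run in runs_of(dif > 0)) {
      if (length(run) >= 4) {
        signals <- dplyr::bind_rows(signals, tibble::tibble(
          period = series$period[run[length(run)] + 1],
          type = "trend_up", length = length(run) + 1L))
      }
    }
    for (run in runs_of(dif < 0)) {
      if (length(run) >= 4) {
        signals <- dplyr::bind_rows(signals, tibble::tibble(
          period = series$period[run[length(run)] + 1],
          type = "trend_down", length = length(run) + 1L))
      }
    }
  }
  structure(list(data = dat, median = med, signals = signals),
            class = "runchart")
}

#' @export
print.runchart <- function(x, ...) {
  cat(sprintf("run chart: %d points, median %.4f, %d signal(s)\n",
              nrow(x$data), x$median, nrow(x$signals)))
  if (nrow(x$signals) > 0) print(x$signals)
  invisible(x)
}

#' @describeIn runchart Per-point tibble with `proportion` and `median`.
#' @param x A `runchart` object.
#' @param ... Unused.
#' @method tidy runchart
#' @export
tidy.runchart <- function(x, ...) x$data

#' @describeIn runchart One-row summary: median, point and signal counts.
#' @method glance runchart
#' @export
glance.runchart <- function(x, ...) {
  tibble::tibble(median = x$median, n_points = nrow(x$data),
                 n_signals = nrow(x$signals))
}

#' @describeIn runchart ggplot of the run chart with its median line.
#' @param object A `runchart` object.
#' @method autoplot runchart
#' @export
autoplot.runchart <- function(object, ...) {
  dat <- object$data
  dat$x <- seq_len(nrow(dat))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$proportion)) +
    ggplot2::geom_hline(yintercept = object$median, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = dat$x,
                                labels = as.character(dat$period)) +
    ggplot2::labs(x = "period", y = "proportion",
                  title = sprintf("run chart (median %.3f)", object$median)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

check_p_bar <- function(p_bar) {
  if (length(p_bar) != 1 || !is.finite(p_bar) || p_bar <= 0 || p_bar >= 1) {
    stop("p_bar must be a single value strictly between 0 and 1",
         call. = FALSE)
  }
}

#' Minimum subgroup size for a workable p-chart
#'
#' Smallest monthly sample size `n` whose expected event count reaches
#' `k`, i.e. the smallest integer with `n * p_bar >= k`. With the default
#' `k = 3` this is the classic rule of thumb for an attribute chart whose
#' within-limit behaviour is approximately normal enough to interpret.
#'
#' @param p_bar Anticipated average proportion, strictly in (0, 1).
#' @param k Required expected number of events per subgroup (default 3).
#' @return Integer sample size.
#' @export
#' @examples
#' min_n_for_expected_events(0.0212)   # 142
min_n_for_expected_events <- function(p_bar, k = 3) {
  check_p_bar(p_bar)
  if (length(k) != 1 || !is.finite(k) || k <= 0) {
    stop("k must be a single positive number", call. = FALSE)
  }
  n <- max(1, floor(k / p_bar))
  if (n * p_bar < k) n <- n + 1
  as.integer(n)
}

#' Minimum subgroup size for a strictly positive lower control limit
#'
#' Smallest monthly sample size `n` for which the 3-sigma lower control
#' limit of a p-chart is strictly positive:
#' `p_bar - 3 * sqrt(p_bar * (1 - p_bar) / n) > 0`, equivalently the
#' smallest integer strictly greater than `9 * (1 - p_bar) / p_bar`. A
#' positive LCL is what lets a chart register *improvement* (a reduction
#' in harm) as a special-cause signal, so this is the binding criterion
#' when planning how many patients to survey. Ties (LCL exactly 0) do not
#' qualify. The algebraic threshold seeds the search and the result is
#' confirmed against the chart's own limit expression, so the returned `n`
#' agrees exactly with the sign of [pchart()] limits even where `9 *
#' (1 - p_bar) / p_bar` lands on an integer and floating-point rounding
#' decides the tie.
#'
#' @inheritParams min_n_for_expected_events
#' @return Integer sample size.
#' @export
#' @examples
#' min_n_for_positive_lcl(0.1764)   # 43
#' min_n_for_positive_lcl(0.5)      # 10: at n = 9 the LCL is exactly 0
min_n_for_positive_lcl <- function(p_bar) {
  check_p_bar(p_bar)
  lcl <- function(n) p_bar - 3 * sqrt(p_bar * (1 - p_bar) / n)
  n <- max(1, floor(9 * (1 - p_bar) / p_bar) + 1)
  while (lcl(n) <= 0) n <- n + 1
  while (n > 1 && lcl(n - 1) > 0) n <- n - 1
  as.integer(n)
}

#' Sample-size plan across a set of measures
#'
#' Computes, for each measure's anticipated average proportion, the
#' workable-chart size ([min_n_for_expected_events()]) and the
#' positive-LCL size ([min_n_for_positive_lcl()]), and recommends the
#' maximum of the chosen criterion over the selected measures — the rarest
#' harm dictates the overall monthly sample.
#'
#' @param p_bars Named numeric vector of average proportions, one per
#'   measure.
#' @param selected Measure names whose sizes drive the recommendation;
#'   defaults to all. Must be a non-empty subset of `names(p_bars)`.
#' @param criterion `"lcl"` (default: strictly positive lower limit, the
#'   improvement-detection requirement) or `"chart"` (expected-events
#'   rule).
#' @return An object of class `sample_size_plan`: a tibble with columns
#'   `measure_id`, `p_bar`, `n_chart`, `n_lcl`, `selected`, plus
#'   attributes `recommended` and `criterion`.
#' @export
#' @examples
#' plan <- sample_size_plan(c(new_pu = 0.0212, catheter = 0.1764))
#' glance(plan)
sample_size_plan <- function(p_bars, selected = names(p_bars),
                             criterion = c("lcl", "chart")) {
  criterion <- match.arg(criterion)
  if (length(p_bars) == 0 || is.null(names(p_bars)) ||
      any(!nzchar(names(p_bars)))) {
    stop("p_bars must be a non-empty named vector", call. = FALSE)
  }
  if (length(selected) == 0) {
    stop("at least one measure must be selected", call. = FALSE)
  }
  if (!all(selected %in% names(p_bars))) {
    stop("selected measures absent from p_bars: ",
         paste(setdiff(selected, names(p_bars)), collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    measure_id = names(p_bars),
    p_bar = unname(p_bars),
    n_chart = purrr::map_int(unname(p_bars), min_n_for_expected_events),
    n_lcl = purrr::map_int(unname(p_bars), min_n_for_positive_lcl),
    selected = names(p_bars) %in% selected
  )
  rec_col <- if (criterion == "lcl") out$n_lcl else out$n_chart
  structure(out,
            recommended = max(rec_col[out$selected]),
            criterion = criterion,
            class = c("sample_size_plan", class(out)))
}

#' @export
print.sample_size_plan <- function(x, ...) {
  NextMethod()
  cat(sprintf("recommended monthly sample: %d patients (criterion: %s)\n",
              attr(x, "recommended"), attr(x, "criterion")))
  invisible(x)
}

#' @describeIn sample_size_plan One-row summary with the recommended
#'   monthly sample size and the criterion that produced it.
#' @param x A `sample_size_plan`.
#' @param ... Unused.
#' @method glance sample_size_plan
#' @export
glance.sample_size_plan <- function(x, ...) {
  tibble::tibble(recommended = attr(x, "recommended"),
                 criterion = attr(x, "criterion"),
                 n_measures = nrow(x), n_selected = sum(x$selected))
}
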