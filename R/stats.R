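# Exact binomial confidence intervals and between-group proportion tests.

#' Exact binomial confidence interval for a proportion
#'
#' Computes the Clopper-Pearson interval from beta-distribution quantiles:
#' `low = qbeta(alpha/2, x, n - x + 1)` (0 exactly when `x = 0`) and
#' `high = qbeta(1 - alpha/2, x + 1, n - x)` (1 exactly when `x = n`).
#' The exact interval is conservative: realised coverage is at least the
#' nominal level. Wilson score and Jeffreys intervals are available as
#' alternatives but are never the default.
#'
#' @param x Number of events (vectorised).
#' @param n Number of trials, `n >= 1`.
#' @param level Confidence level in (0, 1); default 0.95.
#' @param method `"clopper-pearson"` (default), `"wilson"` or `"jeffreys"`.
#' @return A tibble with columns `low` and `high`, one row per input.
#' @export
#' @examples
#' exact_binomial_ci(0, 10)          # low is exactly 0
#' exact_binomial_ci(12, 161)
exact_binomial_ci <- function(x, n, level = 0.95,
                              method = c("clopper-pearson", "wilson",
                                         "jeffreys")) {
  method <- match.arg(method)
  if (length(level) != 1 || !is.finite(level) || level <= 0 || level >= 1) {
    stop("level must be a single value in (0, 1)", call. = FALSE)
  }
  k <- max(length(x), length(n))
  x <- rep_len(x, k)
  n <- rep_len(n, k)
  if (any(n < 1)) stop("n must be at least 1", call. = FALSE)
  if (any(x < 0 | x > n)) stop("x must satisfy 0 <= x <= n", call. = FALSE)
  alpha <- 1 - level
  if (method == "clopper-pearson") {
    low <- ifelse(x == 0, 0, qbeta(alpha / 2, x, n - x + 1))
    high <- ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 1, n - x))
  } else if (method == "jeffreys") {
    low <- ifelse(x == 0, 0, qbeta(alpha / 2, x + 0.5, n - x + 0.5))
    high <- ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 0.5, n - x + 0.5))
  } else {
    z <- qnorm(1 - alpha / 2)
    p <- x / n
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    low <- pmax(0, centre - hw)
    high <- pmin(1, centre + hw)
  }
  tibble::tibble(low = low, high = high)
}

#' Chi-square goodness-of-fit test for observed counts
#'
#' Tests observed category counts against expected proportions with the
#' classic statistic `sum((O - E)^2 / E)`, `E = N * expected`, on
#' `cells - 1` degrees of freedom. When the expected proportions do not
#' exhaust the sample (they sum to less than 1), a complement cell is
#' appended; `total` must then cover the unlisted observations.
#'
#' @param observed Non-negative integer counts per category.
#' @param expected Expected proportions; must sum to 1 within `1e-9`,
#'   unless `total` is supplied, in which case proportions summing to less
#'   than 1 are completed with a complement cell.
#' @param total Total sample size covering the unlisted complement;
#'   only needed for non-exhaustive `expected`.
#' @return A one-row tibble with `statistic`, `df` and `p_value`.
#' @export
#' @examples
#' chisq_gof(c(10, 90), c(0.2, 0.8))
chisq_gof <- function(observed, expected, total = sum(observed)) {
  if (length(observed) != length(expected)) {
    stop("observed and expected must have the same length", call. = FALSE)
  }
  if (any(observed < 0) || any(expected < 0)) {
    stop("counts and proportions must be non-negative", call. = FALSE)
  }
  s <- sum(expected)
  if (s < 1 - 1e-9 && !missing(total)) {
    rest_obs <- total - sum(observed)
    if (rest_obs < 0) {
      stop("total must be at least sum(observed) for complement augmentation",
           call. = FALSE)
    }
    observed <- c(observed, rest_obs)
    expected <- c(expected, 1 - s)
  } else if (abs(s - 1) > 1e-9) {
    stop("expected proportions must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  n <- sum(observed)
  e <- n * expected
  if (any(e <= 0)) stop("every expected count must be positive", call. = FALSE)
  statistic <- sum((observed - e)^2 / e)
  df <- length(observed) - 1L
  tibble::tibble(statistic = statistic, df = df,
                 p_value = pchisq(statistic, df, lower.tail = FALSE))
}

#' Two-sample test of equal proportions
#'
#' Pearson chi-square test on the 2x2 table, without continuity
#' correction, on 1 degree of freedom. Used by [comparison_report()] to
#' compare a group against a reference series.
#'
#' @param x1,n1 Events and trials in the first group.
#' @param x2,n2 Events and trials in the second group.
#' @return A one-row tibble with `statistic`, `df` and `p_value`.
#' @export
#' @examples
#' two_proportion_test(10, 100, 20, 100)
two_proportion_test <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1) stop("both group sizes must be at least 1",
                             call. = FALSE)
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    stop("events must satisfy 0 <= x <= n in each group", call. = FALSE)
  }
  a <- x1; b <- n1 - x1; c <- x2; d <- n2 - x2
  n <- n1 + n2
  denom <- as.numeric(a + b) * (c + d) * (a + c) * (b + d)
  statistic <- if (denom == 0) 0 else n * (a * d - b * c)^2 / denom
  tibble::tibble(statistic = statistic, df = 1L,
                 p_value = pchisq(statistic, 1, lower.tail = FALSE))
}
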