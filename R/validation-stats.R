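# Validation statistics: one-sample t comparison of an experimental group
# against a calculated key point, and the bracketing ("squeeze") test.

#' One-sample t test against a calculated point
#'
#' Tests whether the mean of an experimental group equals a calculated key
#' point: \eqn{t = (\bar x - \mu_0)/(s/\sqrt n)} with `n - 1` degrees of
#' freedom.  A zero-variance sample whose mean equals `mu0` is reported as
#' `t = 0, p = 1` by convention; a zero-variance sample with a different
#' mean is an error (no finite t exists).
#'
#' @param x Numeric vector of group measurements (tension in MPa or LC
#'   fraction), `n >= 2`.
#' @param mu0 The calculated point to test against.
#' @param direction `"two.sided"` (default), `"less"` or `"greater"`.
#' @param alpha Significance level used for the `significant` flag.
#' @return Object of class `hvc_ttest`: list with `statistic`, `df`,
#'   `p_value`, `direction`, `mean`, `mu0`, `alpha`, `significant`.
#' @examples
#' one_sample_t(c(1, 2, 3), mu0 = 0)  # t = 3.46, p ~ 0.074
#' @export
one_sample_t <- function(x, mu0,
                         direction = c("two.sided", "less", "greater"),
                         alpha = 0.05) {
  direction <- match.arg(direction)
  if (!is.numeric(x) || length(x) < 2L || anyNA(x) || any(!is.finite(x)))
    stop("`x` must be a numeric vector of >= 2 finite values",
         call. = FALSE)
  if (!is.numeric(mu0) || length(mu0) != 1L || !is.finite(mu0))
    stop("`mu0` must be a single finite number", call. = FALSE)
  n <- length(x)
  if (stats::sd(x) == 0) {
    if (isTRUE(all.equal(mean(x), mu0)))
      return(structure(
        list(statistic = 0, df = n - 1L, p_value = 1,
             direction = direction, mean = mean(x), mu0 = mu0,
             alpha = alpha, significant = FALSE),
        class = "hvc_ttest"))
    stop("zero-variance sample with mean != mu0: t statistic undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(x, mu = mu0, alternative = direction)
  structure(
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, direction = direction, mean = mean(x),
         mu0 = mu0, alpha = alpha,
         significant = tt$p.value < alpha),
    class = "hvc_ttest")
}

#' @export
print.hvc_ttest <- function(x, ...) {
  cat(sprintf(
    "One-sample t (%s): t = %.4f, df = %d, p = %.4g  [mean %.4g vs %.4g]\n",
    x$direction, x$statistic, x$df, x$p_value, x$mean, x$mu0))
  invisible(x)
}

#' Bracketing ("squeeze") test of a calculated key point
#'
#' Demonstrates that a calculated point lies strictly between two measured
#' groups: a one-sided one-sample t of the lower group against the point
#' (alternative: mean below the point) and of the upper group (alternative:
#' mean above it).  The point is declared bracketed when both one-sided
#' tests are significant at `alpha`.  This formalises the argument that a
#' lethal point fitted from the curve falls between the group that
#' recovered after rewatering and the group that did not.
#'
#' @param lower Numeric vector: the group expected to lie below `point`.
#' @param upper Numeric vector: the group expected to lie above `point`.
#' @param point The calculated key point (MPa tension or LC fraction).
#' @param alpha Significance level for both one-sided tests.
#' @return Object of class `hvc_bracket`: list with `lower_test`,
#'   `upper_test` (each `hvc_ttest`), `point`, `alpha`, and logical
#'   `bracketed`.
#' @examples
#' set.seed(1)
#' bracket_test(rnorm(10, 2.73, 0.03), rnorm(10, 2.93, 0.03), 2.777)
#' @export
bracket_test <- function(lower, upper, point, alpha = 0.05) {
  lo <- one_sample_t(lower, point, direction = "less", alpha = alpha)
  hi <- one_sample_t(upper, point, direction = "greater", alpha = alpha)
  structure(
    list(lower_test = lo, upper_test = hi, point = point, alpha = alpha,
         bracketed = lo$p_value < alpha && hi$p_value < alpha),
    class = "hvc_bracket")
}

#' @export
print.hvc_bracket <- function(x, ...) {
  cat(sprintf("Bracketing test of point %.4g (alpha = %.2g): %s\n",
              x$point, x$alpha,
              if (x$bracketed) "bracketed" else "not bracketed"))
  cat(sprintf("  lower group mean %.4g: p = %.4g (less)\n",
              x$lower_test$mean, x$lower_test$p_value))
  cat(sprintf("  upper group mean %.4g: p = %.4g (greater)\n",
              x$upper_test$mean, x$upper_test$p_value))
  invisible(x)
}

#' Compare differential- and traditional-method points against groups
#'
#' For each experimental group, tests the matching differential-method key
#' point and traditional-method quantile point by two-sided one-sample t
#' tests, and labels each method `"consistent"` (p >= alpha) or as
#' over-/under-estimating the group (significant difference, signed by the
#' point relative to the group mean).
#'
#' Groups are supplied as a named list of numeric vectors; recognised names
#' are `air_entry` (tested against `psi_e` / `psi_12`), `fastest_drop`
#' (`psi_m` / `psi_50`) and `lethal` (`psi_l` / `psi_88`).  Unrecognised
#' names, and pairings whose DM point is absent, are skipped with a
#' message.
#'
#' @param groups Named list of numeric vectors of tension measurements
#'   (MPa).
#' @param keypoints An `hvc_keypoints` object from [dm_key_points()].
#' @param tm An `hvc_tm_points` object from [tm_points()].
#' @param alpha Significance level.
#' @return Data frame with one row per (group, method): columns `group`,
#'   `method`, `point`, `sample_mean`, `statistic`, `p_value`, `verdict`.
#'   An empty `groups` list yields a zero-row data frame.
#' @export
method_comparison_report <- function(groups, keypoints, tm, alpha = 0.05) {
  if (!inherits(keypoints, "hvc_keypoints"))
    stop("`keypoints` must be an hvc_keypoints object", call. = FALSE)
  if (!inherits(tm, "hvc_tm_points"))
    stop("`tm` must be an hvc_tm_points object", call. = FALSE)
  pairing <- list(
    air_entry = c(dm = keypoints$psi_e, tm = tm$psi_12),
    fastest_drop = c(dm = keypoints$psi_m, tm = tm$psi_50),
    lethal = c(dm = keypoints$psi_l, tm = tm$psi_88))
  rows <- list()
  for (g in names(groups)) {
    if (!g %in% names(pairing)) {
      message("method_comparison_report: skipping unrecognised group '",
              g, "'")
      next
    }
    for (m in c("dm", "tm")) {
      point <- pairing[[g]][[m]]
      if (is.na(point)) {
        message("method_comparison_report: ", m, " point for '", g,
                "' absent; skipped")
        next
      }
      tt <- one_sample_t(groups[[g]], point, direction = "two.sided",
                         alpha = alpha)
      verdict <- if (tt$p_value >= alpha) "consistent"
                 else if (point > tt$mean) "overestimates"
                 else "underestimates"
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, method = m, point = point, sample_mean = tt$mean,
        statistic = tt$statistic, p_value = tt$p_value, verdict = verdict,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(group = character(), method = character(),
                      point = numeric(), sample_mean = numeric(),
                      statistic = numeric(), p_value = numeric(),
                      verdict = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
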