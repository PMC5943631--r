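#' Bland-Altman agreement analysis
#'
#' Tukey mean-difference analysis of two methods' paired measurements.
#' Differences are `d = a - b` and means `m = (a + b) / 2`. Alongside the
#' conventional signed summary (mean difference, SD, limits of agreement
#' `mean(d) +/- 1.96 SD(d)`), the report carries the *absolute* mean
#' difference `mean(|d|)` with its own SD: in device-validation work against
#' intra-arterial references the absolute mean difference is often what is
#' reported as the bias, and it never benefits from errors of opposite sign
#' cancelling. Both families are always reported to avoid ambiguity. The
#' trend slope is the least-squares slope of `d` on `m` (a negative slope
#' flags pressure-dependent attenuation).
#'
#' @param pairs `data.frame` (or 2-column matrix) with columns `a` (test
#'   method) and `b` (reference method), mmHg; at least 2 pairs.
#' @param channel `"systolic"` or `"diastolic"`; selects the default validity
#'   threshold (10 or 5 mmHg).
#' @param validity_threshold mmHg; pairs with `|d| <= threshold` (inclusive)
#'   count as within threshold. Default 10 for systolic, 5 for diastolic.
#' @param test `"t"` (paired two-sided t-test, default) or `"wilcoxon"`
#'   (signed-rank) for the paired p-value.
#' @return object of class `agreement_report`: `n`,
#'   `signed_mean_difference`, `absolute_mean_difference`, `sd_signed`,
#'   `sd_absolute`, `limits_of_agreement` (length 2), `paired_p`,
#'   `within_threshold_fraction`, `trend_slope`, `channel`,
#'   `validity_threshold`, plus the per-pair `mean` and `difference` vectors
#'   for plotting.
#' @export
#' @examples
#' pairs <- data.frame(a = c(124, 118, 136), b = c(120, 120, 130))
#' bland_altman(pairs, "systolic")
bland_altman <- function(pairs, channel = c("systolic", "diastolic"),
                         validity_threshold = NULL, test = c("t", "wilcoxon")) {
  channel <- match.arg(channel)
  test <- match.arg(test)
  pairs <- as.data.frame(pairs)
  if (!all(c("a", "b") %in% names(pairs))) {
    if (ncol(pairs) == 2L) names(pairs) <- c("a", "b")
    else stop("`pairs` needs columns `a` and `b`")
  }
  n <- nrow(pairs)
  if (n < 2L) stop("need at least 2 pairs, got ", n)
  if (is.null(validity_threshold)) {
    validity_threshold <- if (channel == "systolic") 10 else 5
  }
  d <- pairs$a - pairs$b
  m <- (pairs$a + pairs$b) / 2
  sd_d <- sd(d)
  trend <- if (var(m) > 0) {
    unname(lm.fit(cbind(1, m), d)$coefficients[2])
  } else NA_real_
  structure(list(
    n = n,
    channel = channel,
    signed_mean_difference = mean(d),
    absolute_mean_difference = mean(abs(d)),
    sd_signed = sd_d,
    sd_absolute = sd(abs(d)),
    limits_of_agreement = c(mean(d) - 1.96 * sd_d, mean(d) + 1.96 * sd_d),
    paired_p = paired_test(d, test),
    within_threshold_fraction = mean(abs(d) <= validity_threshold),
    trend_slope = trend,
    validity_threshold = validity_threshold,
    mean = m,
    difference = d
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (%s, n = %d)\n", x$channel, x$n))
  cat(sprintf("  signed mean difference   %6.2f (SD %.2f) mmHg\n",
              x$signed_mean_difference, x$sd_signed))
  cat(sprintf("  absolute mean difference %6.2f (SD %.2f) mmHg\n",
              x$absolute_mean_difference, x$sd_absolute))
  cat(sprintf("  limits of agreement      [%.2f, %.2f] mmHg\n",
              x$limits_of_agreement[1], x$limits_of_agreement[2]))
  cat(sprintf("  within %.0f mmHg: %.0f%%   trend slope %.3f   paired p %s\n",
              x$validity_threshold, 100 * x$within_threshold_fraction,
              x$trend_slope, format(x$paired_p, digits = 3)))
  invisible(x)
}

#' Paired test of zero mean difference
#'
#' Two-sided paired test that the mean of the differences is zero. With zero
#' variance the test statistic is undefined: by convention the p-value is 1
#' when all differences are exactly 0 and 0 when they are all equal to the
#' same nonzero value.
#'
#' @param differences numeric vector of paired differences (>= 2 values).
#' @param test `"t"` (default) or `"wilcoxon"` signed-rank.
#' @return p-value.
#' @export
paired_test <- function(differences, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  if (length(differences) < 2L) stop("need at least 2 differences")
  if (sd(differences) == 0) {
    return(if (mean(differences) == 0) 1 else 0)
  }
  if (test == "t") {
    t.test(differences, mu = 0)$p.value
  } else {
    suppressWarnings(wilcox.test(differences, mu = 0)$p.value)
  }
}

#' A-priori validity check
#'
#' The validity rule fixed before data collection: any two simultaneous
#' measures must agree within 10 mmHg (systolic) or 5 mmHg (diastolic). The
#' check compares the report's within-threshold fraction against a required
#' fraction, 1.0 by default ("any 2 measures"); a lower required fraction can
#' be configured for population-level criteria.
#'
#' @param report `agreement_report` from [bland_altman()].
#' @param channel `"systolic"` or `"diastolic"`; must match the report.
#' @param required_fraction minimum within-threshold fraction to pass.
#' @return logical: `TRUE` if the report passes.
#' @export
validity_check <- function(report, channel = report$channel,
                           required_fraction = 1.0) {
  channel <- match.arg(channel, c("systolic", "diastolic"))
  if (!identical(channel, report$channel)) {
    stop("report is for channel '", report$channel, "', not '", channel, "'")
  }
  report$within_threshold_fraction >= required_fraction
}

#' Accuracy and variability improvement between two agreement reports
#'
#' Percentage change from a pre-calibration to a post-calibration agreement
#' report: `accuracy_improvement = 100 * (pre_AMD - post_AMD) / pre_AMD`
#' where AMD is the absolute mean difference, and `variability_reduction`
#' analogously on the SD of the absolute differences. Both are returned
#' unrounded and rounded to the nearest integer (half away from zero) for
#' display.
#'
#' @param pre,post `agreement_report`s for the same channel, or bare numeric
#'   `c(amd, sd_absolute)` summaries.
#' @return list with `accuracy_improvement`, `variability_reduction`
#'   (percent, unrounded) and `accuracy_improvement_rounded`,
#'   `variability_reduction_rounded`.
#' @export
#' @examples
#' improvement_metrics(c(10.8, 9.7), c(7.2, 5.1))$accuracy_improvement_rounded
improvement_metrics <- function(pre, post) {
  as_summary <- function(x) {
    if (inherits(x, "agreement_report")) {
      c(amd = x$absolute_mean_difference, sd = x$sd_absolute)
    } else if (is.numeric(x) && length(x) %in% c(1L, 2L)) {
      c(amd = x[1], sd = if (length(x) == 2L) x[2] else NA_real_)
    } else stop("expected an agreement_report or numeric c(amd, sd)")
  }
  a <- as_summary(pre); b <- as_summary(post)
  if (inherits(pre, "agreement_report") && inherits(post, "agreement_report")
      && !identical(pre$channel, post$channel)) {
    stop("pre and post reports are for different channels")
  }
  if (a[["amd"]] <= 0) stop("pre absolute mean difference must be > 0")
  acc <- 100 * (a[["amd"]] - b[["amd"]]) / a[["amd"]]
  vr <- if (is.na(a[["sd"]]) || is.na(b[["sd"]])) NA_real_ else {
    if (a[["sd"]] <= 0) stop("pre sd_absolute must be > 0 for the ",
                             "variability reduction")
    100 * (a[["sd"]] - b[["sd"]]) / a[["sd"]]
  }
  list(accuracy_improvement = acc,
       variability_reduction = vr,
       accuracy_improvement_rounded = round_half_away(acc),
       variability_reduction_rounded = round_half_away(vr))
}

#' Per-pair Bland-Altman plot data
#'
#' @param report `agreement_report`.
#' @return `data.frame` with columns `mean` and `difference`, one row per
#'   pair, suitable for external plotting.
#' @export
agreement_plot_data <- function(report) {
  data.frame(mean = report$mean, difference = report$difference)
}
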