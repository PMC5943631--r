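#' Guideline threshold sets
#'
#' Named hypertension thresholds: a reading is called positive when systolic
#' pressure meets the systolic threshold OR (when a diastolic threshold is
#' defined) diastolic pressure meets the diastolic threshold, both inclusive.
#'
#' Two named defaults ship with the package: `"CHEP"` (the home-monitoring
#' confirmation threshold, 135/85 mmHg) and `"SPRINT"` (the intensive
#' systolic target, 120 mmHg, no diastolic criterion).
#'
#' @param name label for reports.
#' @param systolic systolic threshold in mmHg (> 0).
#' @param diastolic diastolic threshold in mmHg, or `NA` for a systolic-only
#'   rule.
#' @return list of class `threshold_set`.
#' @export
#' @examples
#' threshold_set("CHEP", 135, 85)
threshold_set <- function(name, systolic, diastolic = NA_real_) {
  if (!is.finite(systolic) || systolic <= 0) {
    stop("systolic threshold must be > 0")
  }
  if (!is.na(diastolic) && diastolic <= 0) {
    stop("diastolic threshold must be > 0 or NA")
  }
  structure(list(name = name, systolic = systolic, diastolic = diastolic),
            class = "threshold_set")
}

#' @rdname threshold_set
#' @export
chep_thresholds <- function() threshold_set("CHEP", 135, 85)

#' @rdname threshold_set
#' @export
sprint_thresholds <- function() threshold_set("SPRINT", 120)

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("%s: systolic >= %g%s mmHg\n", x$name, x$systolic,
              if (is.na(x$diastolic)) "" else
                sprintf(" or diastolic >= %g", x$diastolic)))
  invisible(x)
}

#' Classify readings as hypertensive under a threshold set
#'
#' @param readings readings `data.frame` (columns `systolic`, `diastolic`),
#'   one or more rows.
#' @param thresholds a [threshold_set()].
#' @return logical vector of hypertension calls, one per reading.
#' @export
#' @examples
#' r <- data.frame(systolic = c(136, 130, 119), diastolic = c(80, 86, 70))
#' classify_reading(r, chep_thresholds()) # TRUE TRUE FALSE
classify_reading <- function(readings, thresholds) {
  pos <- readings$systolic >= thresholds$systolic
  if (!is.na(thresholds$diastolic)) {
    pos <- pos | (readings$diastolic >= thresholds$diastolic)
  }
  pos
}

#' Cross-tabulate hypertension calls against a reference
#'
#' @param method_calls,reference_calls logical vectors of equal length
#'   (>= 1).
#' @return object of class `concordance_table` with counts `a`
#'   (reference+, method+), `b` (reference+, method-), `c` (reference-,
#'   method+), `d` (reference-, method-).
#' @export
concordance <- function(method_calls, reference_calls) {
  if (length(method_calls) != length(reference_calls)) {
    stop("call vectors differ in length (", length(method_calls), " vs ",
         length(reference_calls), ")")
  }
  if (length(method_calls) < 1L) stop("need at least one call")
  structure(list(a = sum(reference_calls & method_calls),
                 b = sum(reference_calls & !method_calls),
                 c = sum(!reference_calls & method_calls),
                 d = sum(!reference_calls & !method_calls)),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(reference = c("positive", "negative"),
                              method = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Sensitivity of a method's hypertension calls
#'
#' `a / (a + b)`: the fraction of reference-positive measures the method also
#' calls positive.
#'
#' @param table `concordance_table`.
#' @return proportion in \[0, 1\].
#' @export
sensitivity <- function(table) {
  if (table$a + table$b == 0) stop("no reference-positive measures")
  table$a / (table$a + table$b)
}

#' Treatment gap
#'
#' The fraction of reference-hypertensive measures the method calls
#' normotensive, `b / (a + b)` — hypertensive patients a low-reading device
#' would leave untreated. Equal to one minus the [sensitivity()].
#'
#' @param table `concordance_table`.
#' @return proportion in \[0, 1\].
#' @export
#' @examples
#' treatment_gap(concordance(c(rep(TRUE, 8), rep(FALSE, 2)), rep(TRUE, 10)))
treatment_gap <- function(table) {
  if (table$a + table$b == 0) stop("no reference-positive measures")
  table$b / (table$a + table$b)
}

#' One-tailed Fisher exact test on a concordance table
#'
#' Exact hypergeometric tail probability of the observed 2x2 table and all
#' more-extreme tables with the same margins. With `alternative = "greater"`
#' the tail collects tables at least as concordant as observed (count `a` at
#' or above the observed value); `"less"` collects tables where the method
#' misses at least as many reference positives (count `a` at or below
#' observed) — the direction used for treatment-gap comparisons. Degenerate
#' margins (an empty row or column) give p = 1 by convention.
#'
#' @param table `concordance_table` (or list with counts `a`, `b`, `c`, `d`).
#' @param alternative `"greater"` (default) or `"less"`.
#' @return p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact_one_tailed(concordance(rep(c(TRUE, FALSE), each = 10),
#'                                     rep(c(TRUE, FALSE), each = 10)))
fisher_exact_one_tailed <- function(table,
                                    alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  if (any(c(a, b, c, d) < 0)) stop("counts must be >= 0")
  if (a + b + c + d == 0) stop("empty table")
  m <- a + b      # reference positives
  nn <- c + d     # reference negatives
  k <- a + c      # method positives
  if (m == 0 || nn == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - nn):min(k, m)
  tail <- if (alternative == "greater") support[support >= a]
          else support[support <= a]
  min(1, sum(dhyper(tail, m, nn, k)))
}

#' Compare methods' hypertension calls against a reference method
#'
#' For each method and each threshold set, classifies the method's and the
#' reference method's readings, cross-tabulates the calls, and reports
#' sensitivity, treatment gap, and a one-tailed Fisher exact p-value in the
#' direction "the method misses reference positives".
#'
#' @param readings_by_method named list of reading `data.frame`s, one per
#'   method, all aligned row-by-row (same measurement occasions in the same
#'   order).
#' @param reference_method name of the list element to use as reference.
#' @param thresholds list of [threshold_set()]s (default CHEP and SPRINT).
#' Two Fisher p-values are reported. `fisher_p` is the one-tailed test on the
#' paired calls cross-tab in the direction "the method misses reference
#' positives". Because that test conditions on the table margins, a uniform
#' call-rate deficit (the very thing a treatment gap is) moves the margins
#' rather than the association, so `fisher_p_rates` additionally tests the
#' unpaired comparison of positive-call rates — method versus reference, one
#' tailed in the direction "the method calls fewer positives" — which is the
#' comparison that flags an under-reading cuff.
#'
#' @return `data.frame` with one row per method x threshold set: `method`,
#'   `threshold_set`, `n`, `positives`, `reference_positives`, `sensitivity`,
#'   `treatment_gap`, `fisher_p`, `fisher_p_rates`.
#' @export
method_comparison <- function(readings_by_method, reference_method,
                              thresholds = list(chep_thresholds(),
                                                sprint_thresholds())) {
  if (!reference_method %in% names(readings_by_method)) {
    stop("reference method '", reference_method, "' not supplied")
  }
  ref <- readings_by_method[[reference_method]]
  n <- nrow(ref)
  if (!all(vapply(readings_by_method, nrow, 0L) == n)) {
    stop("all methods must supply the same number of aligned readings")
  }
  rows <- list()
  for (th in thresholds) {
    ref_calls <- classify_reading(ref, th)
    for (nm in names(readings_by_method)) {
      calls <- classify_reading(readings_by_method[[nm]], th)
      tab <- concordance(calls, ref_calls)
      has_pos <- tab$a + tab$b > 0
      rows[[length(rows) + 1L]] <- data.frame(
        method = nm, threshold_set = th$name, n = n,
        positives = sum(calls), reference_positives = tab$a + tab$b,
        sensitivity = if (has_pos) sensitivity(tab) else NA_real_,
        treatment_gap = if (has_pos) treatment_gap(tab) else NA_real_,
        fisher_p = fisher_exact_one_tailed(tab, "less"),
        fisher_p_rates = fisher_exact_one_tailed(
          list(a = sum(ref_calls), b = sum(!ref_calls),
               c = sum(calls), d = sum(!calls)), "greater"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
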