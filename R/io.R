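reading_columns <- c("patient_id", "method", "arm", "stage", "order_index",
                     "systolic", "diastolic", "sd_systolic", "sd_diastolic")

#' Read a blood-pressure readings table
#'
#' Comma-separated with a header row and exactly the canonical columns
#' (`patient_id, method, arm, stage, order_index, systolic, diastolic,
#' sd_systolic, sd_diastolic`); an empty SD field means the method reported
#' no per-reading SD. Rows are validated: pressures must be numeric and
#' systolic must exceed diastolic; a violating row is rejected with its line
#' number. Row order is preserved. An empty (header-only) file yields an
#' empty table.
#'
#' @param path CSV file path.
#' @return readings `data.frame`.
#' @seealso [write_readings()]
#' @export
read_readings <- function(path) {
  if (!file.exists(path)) stop("readings file not found: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(reading_columns, names(raw))
  if (length(missing)) {
    stop("readings file ", path, " is missing columns: ",
         paste(missing, collapse = ", "))
  }
  raw <- raw[, reading_columns, drop = FALSE]
  if (nrow(raw) == 0L) {
    out <- data.frame(patient_id = character(), method = character(),
                      arm = character(), stage = character(),
                      order_index = integer(), systolic = numeric(),
                      diastolic = numeric(), sd_systolic = numeric(),
                      sd_diastolic = numeric(), stringsAsFactors = FALSE)
    return(out)
  }
  num <- function(x, col, allow_empty = FALSE) {
    x <- trimws(x)
    empty <- x == "" | is.na(x)
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !empty)
    if (length(bad)) {
      stop("line ", bad[1] + 1L, ": non-numeric ", col, " value '",
           x[bad[1]], "'")
    }
    if (!allow_empty && any(empty)) {
      stop("line ", which(empty)[1] + 1L, ": missing ", col, " value")
    }
    v
  }
  out <- data.frame(
    patient_id = raw$patient_id,
    method = raw$method,
    arm = raw$arm,
    stage = raw$stage,
    order_index = as.integer(num(raw$order_index, "order_index")),
    systolic = num(raw$systolic, "systolic"),
    diastolic = num(raw$diastolic, "diastolic"),
    sd_systolic = num(raw$sd_systolic, "sd_systolic", allow_empty = TRUE),
    sd_diastolic = num(raw$sd_diastolic, "sd_diastolic", allow_empty = TRUE),
    stringsAsFactors = FALSE
  )
  bad_method <- which(!out$method %in% bp_methods)
  if (length(bad_method)) {
    stop("line ", bad_method[1] + 1L, ": unknown method '",
         out$method[bad_method[1]], "'")
  }
  bad <- which(out$systolic <= out$diastolic)
  if (length(bad)) {
    stop("line ", bad[1] + 1L, ": systolic (", out$systolic[bad[1]],
         ") must exceed diastolic (", out$diastolic[bad[1]], ")")
  }
  out
}

#' Write a blood-pressure readings table
#'
#' @param readings readings `data.frame`.
#' @param path output CSV path; absent SDs (`NA`) are written as empty
#'   fields.
#' @return `path`, invisibly.
#' @export
write_readings <- function(readings, path) {
  write.csv(readings[, reading_columns, drop = FALSE], path,
            row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read / write a beat-level pressure series
#'
#' Comma-separated with header `time_s, systolic, diastolic`.
#'
#' @param path CSV file path.
#' @return `data.frame` with `time_s`, `systolic`, `diastolic`.
#' @export
read_beat_series <- function(path) {
  if (!file.exists(path)) stop("beat series file not found: ", path)
  out <- read.csv(path)
  need <- c("time_s", "systolic", "diastolic")
  if (!all(need %in% names(out))) {
    stop("beat series file must have columns: ", paste(need, collapse = ", "))
  }
  if (is.unsorted(out$time_s, strictly = TRUE)) {
    stop("beat series times must be strictly increasing")
  }
  if (any(out$systolic <= out$diastolic)) {
    stop("beat series has systolic <= diastolic samples")
  }
  out[, need]
}

#' @rdname read_beat_series
#' @param series beat series `data.frame`.
#' @export
write_beat_series <- function(series, path) {
  write.csv(series[, c("time_s", "systolic", "diastolic")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize calibration models
#'
#' Writes one row per model: `channel, intercept, slope, family,
#' reference_site, n_training`.
#'
#' @param models list of `calibration_model`s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_models <- function(models, path) {
  rows <- lapply(models, function(m) {
    data.frame(channel = m$channel, intercept = m$intercept, slope = m$slope,
               family = m$family, reference_site = m$reference_site,
               n_training = m$n_training, stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_models
#' @return `read_models()`: list of `calibration_model`s.
#' @export
read_models <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    structure(list(channel = tab$channel[i], intercept = tab$intercept[i],
                   slope = tab$slope[i], family = tab$family[i],
                   reference_site = tab$reference_site[i],
                   n_training = tab$n_training[i]),
              class = "calibration_model")
  })
}

# flatten an agreement report to a one-row data.frame for report tables
agreement_row <- function(report, label) {
  data.frame(label = label, channel = report$channel, n = report$n,
             signed_mean_difference = report$signed_mean_difference,
             absolute_mean_difference = report$absolute_mean_difference,
             sd_signed = report$sd_signed, sd_absolute = report$sd_absolute,
             loa_low = report$limits_of_agreement[1],
             loa_high = report$limits_of_agreement[2],
             paired_p = report$paired_p,
             within_threshold_fraction = report$within_threshold_fraction,
             trend_slope = report$trend_slope, stringsAsFactors = FALSE)
}
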