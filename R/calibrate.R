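#' Fit an affine calibration model
#'
#' Ordinary least squares of the reference pressure on the device value:
#' `reference ~ intercept + slope * device`. This is the per-channel
#' calibration family used throughout: the minimal family expressing both an
#' offset and a gain error. The `"offset"` family constrains the slope to 1
#' and estimates the intercept as the mean reference-minus-device difference.
#'
#' @param pairs `data.frame` (or 2-column matrix) with columns `device` and
#'   `reference`, both in mmHg; at least two pairs with non-identical device
#'   values.
#' @param channel `"systolic"` or `"diastolic"`.
#' @param family `"affine"` (default) or `"offset"`.
#' @param reference_site `"radial"`, `"aorta"` or `NA`; provenance metadata.
#' @return object of class `calibration_model` with fields `channel`,
#'   `intercept` (mmHg), `slope`, `family`, `reference_site`, `n_training`.
#' @export
#' @examples
#' pairs <- data.frame(device = c(100, 120, 140), reference = c(110, 130, 150))
#' fit_affine(pairs, "systolic") # intercept 10, slope 1
fit_affine <- function(pairs, channel = c("systolic", "diastolic"),
                       family = c("affine", "offset"),
                       reference_site = NA_character_) {
  channel <- match.arg(channel)
  family <- match.arg(family)
  pairs <- as.data.frame(pairs)
  if (!all(c("device", "reference") %in% names(pairs))) {
    if (ncol(pairs) == 2L) names(pairs) <- c("device", "reference")
    else stop("`pairs` needs columns `device` and `reference`")
  }
  n <- nrow(pairs)
  if (n < 2L) stop("need at least 2 pairs to fit a calibration, got ", n)
  if (family == "affine") {
    if (var(pairs$device) == 0) {
      stop("degenerate fit: all device values identical")
    }
    fit <- lm.fit(cbind(1, pairs$device), pairs$reference)
    intercept <- unname(fit$coefficients[1])
    slope <- unname(fit$coefficients[2])
  } else {
    intercept <- mean(pairs$reference - pairs$device)
    slope <- 1
  }
  structure(list(channel = channel, intercept = intercept, slope = slope,
                 family = family, reference_site = reference_site,
                 n_training = n),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "Calibration model (%s, %s): calibrated = %.4f + %.4f x device  [n = %d%s]\n",
    x$channel, x$family, x$intercept, x$slope, x$n_training,
    if (is.na(x$reference_site)) "" else paste0(", ref ", x$reference_site)))
  invisible(x)
}

#' Jackknife leave-one-out calibration
#'
#' The jackknife procedure suits the small datasets of catheterization-lab
#' validation studies: for each of the N device/reference pairs in turn, a
#' calibration model is fitted on the other N-1 pairs (the training set) and
#' applied to the held-out device value (the testing set). The held-out
#' calibrated values are what downstream agreement analysis consumes: every
#' calibrated value is predicted by a model that never saw it. A deployed
#' model fitted on all N pairs is returned for reuse on new readings.
#'
#' @inheritParams fit_affine
#' @param pairs at least 3 device/reference pairs.
#' @return object of class `jackknife_result` with `models` (N per-iteration
#'   `calibration_model`s), `holdout` (`data.frame` with `device`,
#'   `reference`, `calibrated`, one row per pair, in input order), and
#'   `deployed` (full-data `calibration_model`).
#' @export
#' @examples
#' pairs <- data.frame(device = c(100, 120, 140, 110),
#'                     reference = c(105, 125, 145, 115))
#' jk <- jackknife_calibrate(pairs, "systolic")
#' jk$holdout$calibrated - jk$holdout$reference # all ~0: exact affine truth
jackknife_calibrate <- function(pairs, channel = c("systolic", "diastolic"),
                                family = c("affine", "offset"),
                                reference_site = NA_character_) {
  channel <- match.arg(channel)
  family <- match.arg(family)
  pairs <- as.data.frame(pairs)
  if (!all(c("device", "reference") %in% names(pairs))) {
    if (ncol(pairs) == 2L) names(pairs) <- c("device", "reference")
    else stop("`pairs` needs columns `device` and `reference`")
  }
  n <- nrow(pairs)
  if (n < 3L) stop("jackknife calibration needs at least 3 pairs, got ", n)
  models <- vector("list", n)
  calibrated <- numeric(n)
  for (i in seq_len(n)) {
    m <- fit_affine(pairs[-i, , drop = FALSE], channel, family,
                    reference_site)
    models[[i]] <- m
    calibrated[i] <- m$intercept + m$slope * pairs$device[i]
  }
  structure(list(models = models,
                 holdout = data.frame(device = pairs$device,
                                      reference = pairs$reference,
                                      calibrated = calibrated),
                 deployed = fit_affine(pairs, channel, family,
                                       reference_site)),
            class = "jackknife_result")
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat("Jackknife calibration,", length(x$models), "leave-one-out iterations\n")
  cat("  deployed: ")
  print(x$deployed)
  res <- x$holdout$calibrated - x$holdout$reference
  cat(sprintf("  held-out residuals: mean %.3f, SD %.3f, mean |r| %.3f mmHg\n",
              mean(res), sd(res), mean(abs(res))))
  invisible(x)
}

#' Apply calibration models to readings
#'
#' Transforms each reading's pressures through the per-channel calibration
#' (`pressure <- intercept + slope * pressure`). A reported per-reading SD is
#' an uncertainty on the same scale as the pressure, so it is multiplied by
#' the (positive) slope; metadata are preserved.
#'
#' @param readings one or more readings (`data.frame` rows).
#' @param systolic_model,diastolic_model `calibration_model`s whose `channel`
#'   fields must match their argument.
#' @return readings `data.frame` with calibrated pressures and SDs.
#' @export
apply_calibration <- function(readings, systolic_model, diastolic_model) {
  if (!inherits(systolic_model, "calibration_model") ||
      !inherits(diastolic_model, "calibration_model")) {
    stop("calibration models must be `calibration_model` objects")
  }
  if (systolic_model$channel != "systolic") {
    stop("systolic_model has channel '", systolic_model$channel, "'")
  }
  if (diastolic_model$channel != "diastolic") {
    stop("diastolic_model has channel '", diastolic_model$channel, "'")
  }
  out <- readings
  out$systolic <- systolic_model$intercept +
    systolic_model$slope * readings$systolic
  out$diastolic <- diastolic_model$intercept +
    diastolic_model$slope * readings$diastolic
  out$sd_systolic <- systolic_model$slope * readings$sd_systolic
  out$sd_diastolic <- diastolic_model$slope * readings$sd_diastolic
  out
}

#' Jackknife-calibrate both channels of a pair table
#'
#' Convenience wrapper running [jackknife_calibrate()] on the systolic and
#' diastolic channels of a simultaneous-pair table (as produced by
#' [assemble_study_pairs()]).
#'
#' @param pair_table `data.frame` with `wrist_systolic`, `wrist_diastolic`,
#'   `reference_systolic`, `reference_diastolic`.
#' @param family calibration family, see [fit_affine()].
#' @param reference_site provenance label.
#' @return list with `systolic` and `diastolic` `jackknife_result`s.
#' @export
calibrate_pairs <- function(pair_table, family = "affine",
                            reference_site = NA_character_) {
  list(
    systolic = jackknife_calibrate(
      data.frame(device = pair_table$wrist_systolic,
                 reference = pair_table$reference_systolic),
      "systolic", family, reference_site),
    diastolic = jackknife_calibrate(
      data.frame(device = pair_table$wrist_diastolic,
                 reference = pair_table$reference_diastolic),
      "diastolic", family, reference_site)
  )
}
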