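bp_methods <- c("wrist_cuff", "upper_arm_oscillometric",
                "upper_arm_auscultatory", "intra_radial", "intra_aortic")
bp_stages <- c("day1_baseline", "conditioning", "radial_simultaneous",
               "aortic_simultaneous", "independent")
bp_arms <- c("left", "right", "none")

# A reporting device never emits systolic <= diastolic: when a strongly
# miscalibrated simulated device would, the diastolic value is capped at
# systolic minus a minimal pulse pressure (mmHg).
enforce_pulse_floor <- function(systolic, diastolic, floor = 5) {
  min(diastolic, systolic - floor)
}

#' Construct a blood-pressure reading
#'
#' One measurement by one method. Wrist-cuff readings carry a per-reading SD
#' (the device's reported measurement uncertainty); for other methods the SD
#' fields may be absent (`NA`).
#'
#' @param patient_id patient identifier.
#' @param method one of `r paste0('"', bp_methods, '"', collapse = ", ")`.
#' @param arm `"left"`, `"right"` or `"none"`.
#' @param systolic,diastolic pressures in mmHg; systolic must exceed
#'   diastolic.
#' @param sd_systolic,sd_diastolic per-reading SDs in mmHg, `NA` when the
#'   method does not report one.
#' @param stage protocol stage, one of
#'   `r paste0('"', bp_stages, '"', collapse = ", ")`.
#' @param order_index 0-based measurement order within the stage.
#' @return one-row `data.frame` with the canonical reading columns.
#' @export
bp_reading <- function(patient_id, method, arm = "none", systolic, diastolic,
                       sd_systolic = NA_real_, sd_diastolic = NA_real_,
                       stage, order_index = 0L) {
  method <- match.arg(method, bp_methods)
  arm <- match.arg(arm, bp_arms)
  stage <- match.arg(stage, bp_stages)
  if (!is.finite(systolic) || !is.finite(diastolic)) {
    stop("pressures must be finite numbers")
  }
  if (systolic <= diastolic) {
    stop("systolic (", format(systolic), ") must exceed diastolic (",
         format(diastolic), ")")
  }
  if (method == "wrist_cuff" && (is.na(sd_systolic) || is.na(sd_diastolic))) {
    stop("wrist_cuff readings must report per-reading SDs")
  }
  if (order_index < 0) stop("order_index must be >= 0")
  data.frame(patient_id = patient_id, method = method, arm = arm,
             stage = stage, order_index = as.integer(order_index),
             systolic = systolic, diastolic = diastolic,
             sd_systolic = sd_systolic, sd_diastolic = sd_diastolic,
             stringsAsFactors = FALSE)
}

#' Define a device transfer model
#'
#' Affine per-channel model of a miscalibrated oscillometric device: reported
#' pressure = intercept + slope x true pressure + Gaussian noise. Stands in
#' for a device's factory (auscultatory) calibration.
#'
#' @param intercept_systolic,intercept_diastolic offsets in mmHg.
#' @param slope_systolic,slope_diastolic dimensionless gains (> 0).
#' @param noise_sd_systolic,noise_sd_diastolic measurement noise SDs in mmHg
#'   (>= 0).
#' @return list of class `device_model`.
#' @export
#' @examples
#' identity_device <- device_model(0, 1, 0, 1, 0, 0)
device_model <- function(intercept_systolic = 0, slope_systolic = 1,
                         intercept_diastolic = 0, slope_diastolic = 1,
                         noise_sd_systolic = 0, noise_sd_diastolic = 0) {
  m <- structure(list(intercept_systolic = intercept_systolic,
                      slope_systolic = slope_systolic,
                      intercept_diastolic = intercept_diastolic,
                      slope_diastolic = slope_diastolic,
                      noise_sd_systolic = noise_sd_systolic,
                      noise_sd_diastolic = noise_sd_diastolic),
                 class = "device_model")
  validate_device_model(m)
}

validate_device_model <- function(m) {
  if (m$slope_systolic <= 0 || m$slope_diastolic <= 0) {
    stop("device slopes must be > 0")
  }
  if (m$noise_sd_systolic < 0 || m$noise_sd_diastolic < 0) {
    stop("device noise SDs must be >= 0")
  }
  invisible(m)
}

#' @export
print.device_model <- function(x, ...) {
  cat("Device transfer model (reported = intercept + slope x true + noise)\n")
  cat(sprintf("  systolic : %+.2f + %.3f x true, noise SD %.2f mmHg\n",
              x$intercept_systolic, x$slope_systolic, x$noise_sd_systolic))
  cat(sprintf("  diastolic: %+.2f + %.3f x true, noise SD %.2f mmHg\n",
              x$intercept_diastolic, x$slope_diastolic, x$noise_sd_diastolic))
  invisible(x)
}

#' Cuff-deflation oscillation envelope (stand-in device front end)
#'
#' Builds the oscillometric envelope for a window of beats: at each cuff
#' pressure on the deflation grid, the oscillation amplitude is the average
#' over beats of a Gaussian kernel centred at the beat's mean arterial
#' pressure (MAP = diastolic + pulse pressure / 3) with width half the pulse
#' pressure. The amplitude is zero outside
#' `[min(diastolic) - width, max(systolic) + width]`. For constant beats the
#' peak sits exactly at the window MAP. This is a documented stand-in for
#' proprietary pulse-waveform processing, not a hemodynamic model.
#'
#' @param window beat series segment (`data.frame` with `systolic`,
#'   `diastolic` columns) covering the cuff acquisition.
#' @param deflation list with `from`, `to`, `by` (mmHg): the cuff deflation
#'   grid; must span the window's pressures. Default: 30 mmHg beyond the
#'   window extremes at 1 mmHg resolution.
#' @return `data.frame` of class `osc_envelope` with columns `pressure`,
#'   `amplitude` (arbitrary units, max 1 for constant beats).
#' @seealso [fixed_ratio_estimate()]
#' @export
oscillometric_envelope <- function(window, deflation = NULL) {
  if (nrow(window) == 0L) stop("empty beat window")
  lo_p <- min(window$diastolic); hi_p <- max(window$systolic)
  if (is.null(deflation)) {
    deflation <- list(from = floor(lo_p - 30), to = ceiling(hi_p + 30), by = 1)
  }
  if (deflation$from > lo_p || deflation$to < hi_p) {
    stop("deflation range [", deflation$from, ", ", deflation$to,
         "] does not span the window pressures [", lo_p, ", ", hi_p, "]")
  }
  grid <- seq(deflation$from, deflation$to, by = deflation$by)
  map <- window$diastolic + (window$systolic - window$diastolic) / 3
  width <- (window$systolic - window$diastolic) / 2
  amp <- rowMeans(vapply(seq_len(nrow(window)), function(i) {
    exp(-((grid - map[i])^2) / (2 * width[i]^2))
  }, numeric(length(grid))))
  support <- grid >= (lo_p - mean(width)) & grid <= (hi_p + mean(width))
  amp[!support] <- 0
  structure(data.frame(pressure = grid, amplitude = amp),
            class = c("osc_envelope", "data.frame"))
}

#' Fixed-ratio systolic/diastolic estimation from an envelope
#'
#' The classical maximum-amplitude + fixed-ratio oscillometric back end: MAP
#' is the cuff pressure of maximum oscillation amplitude; systolic is the
#' pressure above the peak where the amplitude first falls to
#' `systolic_ratio` x maximum, diastolic the pressure below the peak at
#' `diastolic_ratio` x maximum, both located by linear interpolation between
#' grid points.
#'
#' @param envelope output of [oscillometric_envelope()], or any data frame
#'   with `pressure` (increasing) and `amplitude` columns and an interior
#'   maximum.
#' @param ratios length-2 numeric `(systolic_ratio, diastolic_ratio)`, each in
#'   (0, 1]. Defaults (0.55, 0.85) are standard fixed-ratio values.
#' @return list with `systolic`, `diastolic`, `map` (mmHg).
#' @export
#' @examples
#' grid <- 60:140
#' tri <- data.frame(pressure = grid, amplitude = 1 - abs(grid - 100) / 40)
#' fixed_ratio_estimate(tri, c(0.55, 0.85)) # 118 / 94, MAP 100
fixed_ratio_estimate <- function(envelope, ratios = c(0.55, 0.85)) {
  if (any(ratios <= 0) || any(ratios > 1)) stop("ratios must be in (0, 1]")
  p <- envelope$pressure; a <- envelope$amplitude
  k <- which.max(a)
  if (k == 1L || k == length(a)) {
    stop("envelope has no interior peak (monotone amplitude)")
  }
  peak <- a[k]; map <- p[k]
  cross <- function(target, dir) {
    idx <- if (dir > 0) seq(k, length(a)) else seq(k, 1L)
    below <- which(a[idx] <= target)
    if (!length(below)) stop("ratio crossing falls outside the pressure grid")
    j <- idx[below[1]]
    if (a[j] == target || j == k) return(p[j])
    jprev <- j - dir
    p[jprev] + (p[j] - p[jprev]) * (a[jprev] - target) / (a[jprev] - a[j])
  }
  list(systolic = cross(ratios[1] * peak, +1L),
       diastolic = cross(ratios[2] * peak, -1L),
       map = map)
}

#' Simulate one wrist-cuff device reading from a beat window
#'
#' The reading is an affine transform of the window-mean pressure plus
#' Gaussian measurement noise. The reported per-reading SD propagates the
#' intraphysiological beat-to-beat variability within the acquisition window
#' through the device gain and combines it in quadrature with the device
#' noise: `sd = sqrt(slope^2 * var(beats) + noise_sd^2)`.
#'
#' @param window beat series segment the cuff acquisition spans.
#' @param model [device_model()].
#' @param seed integer seed or `NULL`.
#' @param patient_id,arm,stage,order_index reading metadata.
#' @return one-row reading `data.frame` with method `"wrist_cuff"`.
#' @export
device_reading <- function(window, model, seed = NULL,
                           patient_id = "P000", arm = "left",
                           stage = "radial_simultaneous", order_index = 0L) {
  if (nrow(window) == 0L) stop("empty beat window")
  validate_device_model(model)
  vs <- if (nrow(window) > 1L) var(window$systolic) else 0
  vd <- if (nrow(window) > 1L) var(window$diastolic) else 0
  with_seed(seed, {
    sys <- model$intercept_systolic +
      model$slope_systolic * mean(window$systolic) +
      rnorm(1, 0, model$noise_sd_systolic)
    dia <- model$intercept_diastolic +
      model$slope_diastolic * mean(window$diastolic) +
      rnorm(1, 0, model$noise_sd_diastolic)
    dia <- enforce_pulse_floor(sys, dia)
    bp_reading(patient_id, "wrist_cuff", arm, sys, dia,
               sd_systolic = sqrt(model$slope_systolic^2 * vs +
                                    model$noise_sd_systolic^2),
               sd_diastolic = sqrt(model$slope_diastolic^2 * vd +
                                     model$noise_sd_diastolic^2),
               stage = stage, order_index = order_index)
  })
}

#' Simulate an auscultatory reading from a beat window
#'
#' Observer reading = window-mean pressure + Gaussian observer noise, rounded
#' to the nearest scale unit (2 mmHg by default, half away from zero — the
#' sphygmomanometer terminal-digit convention). In double-observer mode the
#' returned pressures are the average of two independent observers' rounded
#' readings.
#'
#' @param window beat series segment.
#' @param observer list with `noise_sd_systolic`, `noise_sd_diastolic`
#'   (mmHg), `rounding_unit` (mmHg) and `n_observers` (1 or 2).
#' @param seed integer seed or `NULL`.
#' @param patient_id,arm,stage,order_index reading metadata.
#' @return one-row reading `data.frame` with method
#'   `"upper_arm_auscultatory"`; SD fields absent (`NA`).
#' @export
auscultatory_reading <- function(window,
                                 observer = list(noise_sd_systolic = 3,
                                                 noise_sd_diastolic = 2,
                                                 rounding_unit = 2,
                                                 n_observers = 2L),
                                 seed = NULL, patient_id = "P000",
                                 arm = "left", stage = "day1_baseline",
                                 order_index = 0L) {
  if (nrow(window) == 0L) stop("empty beat window")
  unit <- observer$rounding_unit %||% 2
  nobs <- observer$n_observers %||% 1L
  with_seed(seed, {
    one <- function() {
      c(round_half_away(mean(window$systolic) +
                          rnorm(1, 0, observer$noise_sd_systolic), unit),
        round_half_away(mean(window$diastolic) +
                          rnorm(1, 0, observer$noise_sd_diastolic), unit))
    }
    obs <- vapply(seq_len(nobs), function(i) one(), numeric(2))
    bp_reading(patient_id, "upper_arm_auscultatory", arm,
               systolic = mean(obs[1, ]),
               diastolic = enforce_pulse_floor(mean(obs[1, ]), mean(obs[2, ]),
                                               floor = unit),
               stage = stage, order_index = order_index)
  })
}
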