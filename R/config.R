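#' Default run configuration
#'
#' Returns the full nested configuration used by the generator, the protocol,
#' the calibration, and the classification stages. Every value can be
#' overridden, either programmatically (modify the returned list) or through a
#' YAML configuration file read with [read_config()].
#'
#' Cohort defaults reproduce the marginal distributions of a catheterization
#' cohort of mostly older, predominantly male, largely hypertensive patients:
#' central aortic systolic 133.4 (SD 22.0, range 96.7-179.3) mmHg, aortic
#' diastolic 67.4 (SD 8.7, range 50.6-85.1) mmHg, radial-minus-aortic systolic
#' augmentation mean 12.3 (SD 10) mmHg, diastolic augmentation mean -1.2 mmHg,
#' hypertension prevalence 75%.
#'
#' The default wrist device model is deliberately miscalibrated
#' (systolic: intercept -5, slope 0.95, noise SD 6; diastolic: intercept +14,
#' slope 1.0, noise SD 4) so that precalibration absolute mean differences
#' fall in the clinically reported 10-16 mmHg regime; it is illustrative
#' plumbing, not a model of any particular commercial device.
#'
#' @param ... named top-level sections to override, e.g.
#'   `default_config(cohort = list(n = 10))` merges into the defaults.
#' @return Nested named list with sections `seed`, `cohort`, `beats`,
#'   `device`, `upper_arm_device`, `observer`, `protocol`, `calibration`,
#'   `thresholds`, `independent`, `output_dir`.
#' @seealso [read_config()], [run_pipeline()]
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$cohort$n
default_config <- function(...) {
  cfg <- list(
    seed = 20180425L,
    cohort = list(
      n = 20L,
      prop_male = 0.75,
      age = list(mean = 62.0, sd = 9.0, min = 43, max = 77),
      bmi = list(mean = 30.6, sd = 5.7, min = 21, max = 45.4),
      wrist_circumference = list(mean = 18.5, sd = 1.5, min = 15.5, max = 21.5),
      hypertension_prevalence = 0.75,
      aortic_systolic = list(mean = 133.4, sd = 22.0, min = 96.7, max = 179.3),
      aortic_diastolic = list(mean = 67.4, sd = 8.7, min = 50.6, max = 85.1),
      systolic_augmentation = list(mean = 12.3, sd = 10.0),
      diastolic_augmentation = list(mean = -1.2, sd = 1.5)
    ),
    beats = list(
      lag1_correlation = 0.7,
      # marginal SDs chosen so the expected max-minus-min of a 25-sample
      # (240 s at 10 s) series is 20 mmHg systolic / 10 mmHg diastolic
      variability_scale_systolic = 20 / ar1_range25_constant,
      variability_scale_diastolic = 10 / ar1_range25_constant,
      window_duration = 60,
      window_step = 10
    ),
    device = list(
      intercept_systolic = -5, slope_systolic = 0.95, noise_sd_systolic = 6,
      intercept_diastolic = 14, slope_diastolic = 1.0, noise_sd_diastolic = 4
    ),
    upper_arm_device = list(
      intercept_systolic = -12, slope_systolic = 1.0, noise_sd_systolic = 5,
      intercept_diastolic = 0, slope_diastolic = 1.0, noise_sd_diastolic = 4
    ),
    observer = list(noise_sd_systolic = 3, noise_sd_diastolic = 2,
                    rounding_unit = 2, n_observers = 2L),
    protocol = list(
      min_age = 19,
      wrist_range = c(13.5, 23),
      bilateral_systolic_tolerance = 10,
      bilateral_diastolic_tolerance = 5
    ),
    calibration = list(family = "affine", reference_site = "aorta"),
    thresholds = list(
      list(name = "CHEP", systolic = 135, diastolic = 85),
      list(name = "SPRINT", systolic = 120, diastolic = NA_real_)
    ),
    independent = list(n_measurements = 375L, n_participants = 97L),
    output_dir = "wristcal-run"
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("overrides must be named top-level config sections")
    }
    for (nm in names(overrides)) {
      cfg[[nm]] <- modify_list(cfg[[nm]], overrides[[nm]])
    }
  }
  validate_config(cfg)
  cfg
}

# recursive list merge: values in `new` replace values in `base`
modify_list <- function(base, new) {
  if (!is.list(base) || !is.list(new)) return(new)
  for (nm in names(new)) base[[nm]] <- modify_list(base[[nm]], new[[nm]])
  base
}

#' Read a run configuration from a YAML file
#'
#' Keys present in the file override the corresponding defaults from
#' [default_config()]; absent keys keep their default values. The merged
#' configuration is validated against the module preconditions before it is
#' returned.
#'
#' @param path path to a YAML file whose top-level keys are configuration
#'   sections.
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- modify_list(default_config(), user)
  validate_config(cfg)
  cfg
}

#' Write a configuration to a YAML file
#'
#' @param config configuration list, e.g. from [default_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

validate_config <- function(cfg) {
  co <- cfg$cohort
  if (!is.numeric(co$n) || co$n < 1) stop("cohort$n must be >= 1")
  if (co$aortic_systolic$mean <= co$aortic_diastolic$mean) {
    stop("configured mean aortic systolic must exceed mean aortic diastolic")
  }
  for (fld in c("age", "bmi", "wrist_circumference",
                "aortic_systolic", "aortic_diastolic")) {
    f <- co[[fld]]
    if (f$sd < 0) stop("cohort$", fld, "$sd must be >= 0")
    if (f$min > f$max) stop("cohort$", fld, ": min > max")
  }
  if (co$hypertension_prevalence < 0 || co$hypertension_prevalence > 1) {
    stop("hypertension_prevalence must be in [0, 1]")
  }
  b <- cfg$beats
  if (b$lag1_correlation <= -1 || b$lag1_correlation >= 1) {
    stop("beats$lag1_correlation must be in (-1, 1)")
  }
  if (b$variability_scale_systolic < 0 || b$variability_scale_diastolic < 0) {
    stop("beat variability scales must be >= 0")
  }
  if (b$window_step <= 0 || b$window_duration < b$window_step) {
    stop("beats window: need duration >= step > 0")
  }
  validate_device_model(do.call(device_model, cfg$device))
  validate_device_model(do.call(device_model, cfg$upper_arm_device))
  if (!cfg$calibration$family %in% c("affine", "offset")) {
    stop("calibration$family must be 'affine' or 'offset'")
  }
  if (!cfg$calibration$reference_site %in% c("radial", "aorta")) {
    stop("calibration$reference_site must be 'radial' or 'aorta'")
  }
  for (th in cfg$thresholds) {
    if (!is.na(th$systolic) && th$systolic <= 0) stop("thresholds must be > 0")
  }
  invisible(cfg)
}
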