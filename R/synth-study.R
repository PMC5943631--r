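#' Simulate a full two-day validation study
#'
#' Generates every reading of the two-day protocol for each cohort patient,
#' plus an independent double-observer auscultatory comparison set.
#'
#' Day 1: four bilateral screening readings (two observers x two arms,
#' single-observer auscultatory method) and four upper-arm baseline readings.
#' Day 2 (ten readings per patient): two conditioning wrist readings, then two
#' wrist readings each paired with a simultaneous intra-radial reading, then
#' two wrist readings each paired with a simultaneous intra-aortic reading.
#' Simultaneity is implemented as an identical underlying beat window per
#' pair: the radial window is the aortic window shifted by the patient's
#' augmentation offsets, the intra-arterial reference is the exact window
#' mean, and the wrist reading is the device model applied to the same
#' window.
#'
#' The independent set emulates a clinical archive of paired wrist and
#' double-observer auscultatory measurements (375 measurements over 97
#' participants by default), each pair again sharing one beat window.
#'
#' @param cohort cohort `data.frame` from [simulate_cohort()].
#' @param config full run configuration ([default_config()]); the `beats`,
#'   `observer` and `independent` sections are used.
#' @param device wrist [device_model()]; defaults to the configured one.
#' @param seed integer seed or `NULL`.
#' @return list of class `study_dataset` with elements `readings` (all Day-1
#'   and Day-2 readings), `independent` (the independent comparison set),
#'   `windows` (true beat-window means underlying each simultaneous or
#'   independent measurement), `cohort`, and `independent_cohort`.
#' @export
#' @examples
#' cohort <- simulate_cohort(4, seed = 1)
#' cfg <- default_config(independent = list(n_measurements = 8L,
#'                                          n_participants = 4L))
#' study <- simulate_study(cohort, cfg, seed = 2)
#' table(study$readings$stage)
simulate_study <- function(cohort, config = default_config(),
                           device = do.call(device_model, config$device),
                           seed = NULL) {
  if (nrow(cohort) == 0L) stop("cohort must be non-empty")
  validate_device_model(device)
  bc <- config$beats
  obs1 <- modify_list(config$observer, list(n_observers = 1L))
  with_seed(seed, {
    readings <- list(); windows <- list()
    win <- function(profile, site) {
      simulate_beat_series(profile, site, duration = bc$window_duration,
                           step = bc$window_step,
                           lag1_correlation = bc$lag1_correlation)
    }
    shift_radial <- function(w, profile) {
      w$systolic <- w$systolic + profile$systolic_augmentation
      w$diastolic <- w$diastolic + profile$diastolic_augmentation
      attr(w, "site") <- "radial"
      w
    }
    note_window <- function(pid, stage, k, site, w) {
      windows[[length(windows) + 1L]] <<- data.frame(
        patient_id = pid, stage = stage, order_index = k, site = site,
        mean_systolic = mean(w$systolic), mean_diastolic = mean(w$diastolic),
        stringsAsFactors = FALSE)
    }
    add <- function(r) readings[[length(readings) + 1L]] <<- r

    for (i in seq_len(nrow(cohort))) {
      p <- cohort[i, ]
      pid <- p$patient_id
      # Day 1: bilateral auscultatory screen, two observers per arm
      for (arm in c("left", "right")) {
        w <- win(p, "aorta")
        for (k in 0:1) {
          add(auscultatory_reading(w, obs1, patient_id = pid, arm = arm,
                                   stage = "day1_baseline", order_index = k))
        }
      }
      # Day 1: four upper-arm baseline readings, ~1 min apart
      for (k in 0:3) {
        w <- win(p, "aorta")
        add(oscillometric_arm_reading(w, do.call(device_model,
                                                 config$upper_arm_device),
                                      patient_id = pid, arm = "left",
                                      stage = "day1_baseline",
                                      order_index = k))
      }
      # Day 2: two conditioning wrist readings (discarded downstream)
      for (k in 0:1) {
        w <- shift_radial(win(p, "aorta"), p)
        add(device_reading(w, device, patient_id = pid, arm = "left",
                           stage = "conditioning", order_index = k))
      }
      # Day 2: simultaneous wrist + intra-arterial pairs
      for (stage in c("radial_simultaneous", "aortic_simultaneous")) {
        for (k in 0:1) {
          wa <- win(p, "aorta")
          wr <- shift_radial(wa, p)
          add(device_reading(wr, device, patient_id = pid, arm = "left",
                             stage = stage, order_index = k))
          if (stage == "radial_simultaneous") {
            add(bp_reading(pid, "intra_radial", "right",
                           mean(wr$systolic), mean(wr$diastolic),
                           stage = stage, order_index = k))
          } else {
            add(bp_reading(pid, "intra_aortic", "none",
                           mean(wa$systolic), mean(wa$diastolic),
                           stage = stage, order_index = k))
          }
          note_window(pid, stage, k, "radial", wr)
          note_window(pid, stage, k, "aorta", wa)
        }
      }
    }

    # independent paired wrist / double-observer auscultatory archive
    ind <- config$independent
    n_meas <- as.integer(ind$n_measurements %||% 0L)
    indep <- list(); indep_cohort <- NULL
    if (n_meas > 0L) {
      n_part <- as.integer(ind$n_participants)
      if (n_part < 1L || n_part > n_meas) {
        stop("independent set: need 1 <= n_participants <= n_measurements")
      }
      indep_cohort <- simulate_cohort(n_part, config$cohort)
      indep_cohort$patient_id <- sprintf("I%03d", seq_len(n_part))
      per <- rep(n_meas %/% n_part, n_part)
      extra <- n_meas %% n_part
      if (extra > 0L) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
      for (i in seq_len(n_part)) {
        p <- indep_cohort[i, ]
        for (k in seq_len(per[i]) - 1L) {
          w <- shift_radial(win(p, "aorta"), p)
          indep[[length(indep) + 1L]] <-
            device_reading(w, device, patient_id = p$patient_id,
                           arm = "left", stage = "independent",
                           order_index = k)
          indep[[length(indep) + 1L]] <-
            auscultatory_reading(w, config$observer,
                                 patient_id = p$patient_id, arm = "right",
                                 stage = "independent", order_index = k)
          note_window(p$patient_id, "independent", k, "radial", w)
        }
      }
    }

    structure(list(readings = do.call(rbind, readings),
                   independent = if (length(indep)) do.call(rbind, indep),
                   windows = do.call(rbind, windows),
                   cohort = cohort,
                   independent_cohort = indep_cohort),
              class = "study_dataset")
  })
}

# upper-arm oscillometric reading: affine device model on the window mean;
# no per-reading SD (consumer upper-arm cuffs report none)
oscillometric_arm_reading <- function(window, model, seed = NULL,
                                      patient_id = "P000", arm = "left",
                                      stage = "day1_baseline",
                                      order_index = 0L) {
  if (nrow(window) == 0L) stop("empty beat window")
  validate_device_model(model)
  with_seed(seed, {
    sys <- model$intercept_systolic +
      model$slope_systolic * mean(window$systolic) +
      rnorm(1, 0, model$noise_sd_systolic)
    dia <- model$intercept_diastolic +
      model$slope_diastolic * mean(window$diastolic) +
      rnorm(1, 0, model$noise_sd_diastolic)
    dia <- enforce_pulse_floor(sys, dia)
    bp_reading(patient_id, "upper_arm_oscillometric", arm, sys, dia,
               stage = stage, order_index = order_index)
  })
}

#' Simulate upper-arm readings paired to the study's aortic windows
#'
#' Produces one upper-arm oscillometric reading per Day-2 aortic beat window,
#' so that upper-arm calls can be cross-tabulated measure-by-measure against
#' the intra-aortic reference in the threshold comparison. The default
#' upper-arm model under-reads systolic pressure by 12 mmHg relative to the
#' aorta, emulating an uncalibrated consumer cuff at risk of a treatment gap.
#'
#' @param study `study_dataset` from [simulate_study()].
#' @param model upper-arm [device_model()].
#' @param seed integer seed or `NULL`.
#' @return readings `data.frame`, method `"upper_arm_oscillometric"`, stage
#'   `"aortic_simultaneous"`, aligned with the study's aortic references by
#'   `patient_id` and `order_index`.
#' @export
simulate_upper_arm_readings <- function(study,
                                        model = do.call(
                                          device_model,
                                          default_config()$upper_arm_device),
                                        seed = NULL) {
  w <- study$windows
  w <- w[w$stage == "aortic_simultaneous" & w$site == "aorta", , drop = FALSE]
  if (nrow(w) == 0L) stop("study contains no aortic windows")
  validate_device_model(model)
  with_seed(seed, {
    out <- lapply(seq_len(nrow(w)), function(i) {
      sys <- model$intercept_systolic +
        model$slope_systolic * w$mean_systolic[i] +
        rnorm(1, 0, model$noise_sd_systolic)
      dia <- model$intercept_diastolic +
        model$slope_diastolic * w$mean_diastolic[i] +
        rnorm(1, 0, model$noise_sd_diastolic)
      bp_reading(w$patient_id[i], "upper_arm_oscillometric", "left",
                 sys, enforce_pulse_floor(sys, dia),
                 stage = "aortic_simultaneous", order_index = w$order_index[i])
    })
    do.call(rbind, out)
  })
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("Synthetic validation study\n")
  cat("  cohort:", nrow(x$cohort), "patients,",
      nrow(x$readings), "protocol readings\n")
  if (!is.null(x$independent)) {
    cat("  independent set:", nrow(x$independent) / 2L, "paired measurements,",
        nrow(x$independent_cohort), "participants\n")
  }
  invisible(x)
}
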