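#' Eligibility screening for the validation protocol
#'
#' Applies the inclusion/exclusion rules: age at least 19 years, wrist
#' circumference within the cuff's admissible range (13.5-23 cm inclusive by
#' default), and none of the clinical exclusion flags (previous percutaneous
#' coronary intervention or bypass graft, aortic aneurysm, peripheral
#' vascular disease, aortic stenosis, arrhythmia, tremor, carotid bruit).
#'
#' @param profile one-row patient profile with `patient_id`, `age`,
#'   `wrist_circumference`.
#' @param flags named logical vector or list of exclusion indicators; any
#'   `TRUE` entry makes the patient ineligible, with the flag's name recorded
#'   as the reason.
#' @param min_age minimum age in years (inclusive).
#' @param wrist_range admissible wrist circumference in cm, inclusive bounds.
#' @return list of class `eligibility_decision` with `patient_id`,
#'   `eligible`, `reasons` (character vector, empty iff eligible).
#' @export
#' @examples
#' p <- data.frame(patient_id = "P001", age = 62, wrist_circumference = 18)
#' eligibility_filter(p)$eligible
eligibility_filter <- function(profile, flags = logical(0),
                               min_age = 19, wrist_range = c(13.5, 23)) {
  reasons <- character(0)
  if (profile$age < min_age) reasons <- c(reasons, "age")
  if (profile$wrist_circumference < wrist_range[1] ||
      profile$wrist_circumference > wrist_range[2]) {
    reasons <- c(reasons, "wrist_circumference")
  }
  flags <- unlist(flags)
  if (length(flags) && any(as.logical(flags))) {
    nm <- names(flags)
    if (is.null(nm)) nm <- paste0("flag", seq_along(flags))
    reasons <- c(reasons, nm[as.logical(flags)])
  }
  structure(list(patient_id = profile$patient_id,
                 eligible = length(reasons) == 0L,
                 reasons = reasons),
            class = "eligibility_decision")
}

#' @export
print.eligibility_decision <- function(x, ...) {
  cat(x$patient_id, if (x$eligible) "eligible" else
    paste("ineligible:", paste(x$reasons, collapse = ", ")), "\n")
  invisible(x)
}

#' Bilateral arm-equality screen
#'
#' The wrist cuff cannot sit on the cannulated arm, so patients are screened
#' for between-arm blood pressure equality: the two observers' auscultatory
#' readings are averaged per arm and the patient passes iff the between-arm
#' differences are within +/-10 mmHg systolic and +/-5 mmHg diastolic
#' (inclusive). Unequal arms suggest undiagnosed peripheral vascular disease.
#'
#' @param left,right two-row reading `data.frame`s (one row per observer) for
#'   the left and right arm.
#' @param systolic_tolerance,diastolic_tolerance inclusive limits in mmHg.
#' @return list of class `bilateral_screen` with `pass`, `delta_systolic`,
#'   `delta_diastolic` (left-minus-right arm-mean differences, mmHg).
#' @export
bilateral_equality_screen <- function(left, right,
                                      systolic_tolerance = 10,
                                      diastolic_tolerance = 5) {
  if (nrow(left) != 2L || nrow(right) != 2L) {
    stop("expected exactly 2 readings (one per observer) per arm; got ",
         nrow(left), " left, ", nrow(right), " right")
  }
  ds <- mean(left$systolic) - mean(right$systolic)
  dd <- mean(left$diastolic) - mean(right$diastolic)
  structure(list(pass = abs(ds) <= systolic_tolerance &&
                   abs(dd) <= diastolic_tolerance,
                 delta_systolic = ds, delta_diastolic = dd),
            class = "bilateral_screen")
}

#' @export
print.bilateral_screen <- function(x, ...) {
  cat(sprintf("bilateral screen: %s (delta %.1f/%.1f mmHg)\n",
              if (x$pass) "pass" else "fail",
              x$delta_systolic, x$delta_diastolic))
  invisible(x)
}

#' Screen a whole study's Day-1 readings
#'
#' Runs [bilateral_equality_screen()] per patient over the Day-1
#' auscultatory readings and returns a screening report table.
#'
#' @param readings readings `data.frame`; rows with
#'   `stage == "day1_baseline"` and method `"upper_arm_auscultatory"` are
#'   used.
#' @param ... passed to [bilateral_equality_screen()].
#' @return `data.frame` with `patient_id`, `pass`, `delta_systolic`,
#'   `delta_diastolic`.
#' @export
screen_study <- function(readings, ...) {
  d1 <- readings[readings$stage == "day1_baseline" &
                   readings$method == "upper_arm_auscultatory", , drop = FALSE]
  if (nrow(d1) == 0L) stop("no Day-1 auscultatory readings to screen")
  out <- lapply(split(d1, d1$patient_id), function(r) {
    s <- bilateral_equality_screen(r[r$arm == "left", , drop = FALSE],
                                   r[r$arm == "right", , drop = FALSE], ...)
    data.frame(patient_id = r$patient_id[1], pass = s$pass,
               delta_systolic = s$delta_systolic,
               delta_diastolic = s$delta_diastolic,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$patient_id), , drop = FALSE]
}

#' Assemble simultaneous wrist/intra-arterial pairs from a Day-2 session
#'
#' Discards the two conditioning wrist readings and pairs, within each
#' simultaneous stage, the wrist reading of order index k with the
#' intra-arterial reading of order index k (simultaneous acquisition shares
#' the order index by construction).
#'
#' @param session readings `data.frame` for one patient's Day 2: 2
#'   conditioning wrist readings, 2 wrist + 2 intra-radial readings (stage
#'   `radial_simultaneous`) and 2 wrist + 2 intra-aortic readings (stage
#'   `aortic_simultaneous`).
#' @return list with `radial` and `aortic`: each a `data.frame` of pairs with
#'   columns `patient_id`, `stage`, `order_index`, `wrist_systolic`,
#'   `wrist_diastolic`, `wrist_sd_systolic`, `wrist_sd_diastolic`,
#'   `reference_method`, `reference_systolic`, `reference_diastolic`.
#' @export
assemble_day2_pairs <- function(session) {
  if (length(unique(session$patient_id)) != 1L) {
    stop("session must contain exactly one patient")
  }
  pick <- function(stage, method, n_expected) {
    r <- session[session$stage == stage & session$method == method, ,
                 drop = FALSE]
    if (nrow(r) != n_expected) {
      stop("incomplete stage '", stage, "': expected ", n_expected, " ",
           method, " readings, found ", nrow(r))
    }
    r[order(r$order_index), , drop = FALSE]
  }
  cond <- session[session$stage == "conditioning", , drop = FALSE]
  if (nrow(cond) != 2L) {
    stop("incomplete stage 'conditioning': expected 2 readings, found ",
         nrow(cond))
  }
  pair_stage <- function(stage, ref_method) {
    wrist <- pick(stage, "wrist_cuff", 2L)
    ref <- pick(stage, ref_method, 2L)
    if (!identical(wrist$order_index, ref$order_index)) {
      stop("mismatched order indices in stage '", stage, "'")
    }
    data.frame(patient_id = wrist$patient_id, stage = stage,
               order_index = wrist$order_index,
               wrist_systolic = wrist$systolic,
               wrist_diastolic = wrist$diastolic,
               wrist_sd_systolic = wrist$sd_systolic,
               wrist_sd_diastolic = wrist$sd_diastolic,
               reference_method = ref$method,
               reference_systolic = ref$systolic,
               reference_diastolic = ref$diastolic,
               stringsAsFactors = FALSE)
  }
  list(radial = pair_stage("radial_simultaneous", "intra_radial"),
       aortic = pair_stage("aortic_simultaneous", "intra_aortic"))
}

#' Assemble Day-2 pairs for every patient in a study
#'
#' @param readings readings `data.frame` covering the Day-2 stages for one or
#'   more patients.
#' @return list with `radial` and `aortic` pair tables stacked over patients.
#' @seealso [assemble_day2_pairs()]
#' @export
assemble_study_pairs <- function(readings) {
  day2 <- readings[readings$stage %in% c("conditioning", "radial_simultaneous",
                                         "aortic_simultaneous"), , drop = FALSE]
  per <- lapply(split(day2, day2$patient_id), assemble_day2_pairs)
  list(radial = do.call(rbind, c(lapply(per, `[[`, "radial"),
                                 list(make.row.names = FALSE))),
       aortic = do.call(rbind, c(lapply(per, `[[`, "aortic"),
                                 list(make.row.names = FALSE))))
}
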