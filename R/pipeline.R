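# improvement metrics are undefined at a zero pre-calibration AMD (already
# perfect agreement); report NAs instead of failing the run
safe_improvement <- function(pre, post) {
  if (pre$absolute_mean_difference <= 0 || pre$sd_absolute <= 0) {
    return(list(accuracy_improvement = NA_real_,
                variability_reduction = NA_real_,
                accuracy_improvement_rounded = NA_real_,
                variability_reduction_rounded = NA_real_))
  }
  improvement_metrics(pre, post)
}

#' Run the full calibration-and-validation pipeline
#'
#' Composes all stages under one configuration and seed: cohort and study
#' simulation, Day-1 bilateral screening, assembly of simultaneous Day-2
#' pairs, jackknife calibration against the radial and aortic references,
#' pre- and post-calibration Bland-Altman agreement (post-calibration
#' agreement uses held-out calibrated values only), the independent-dataset
#' comparison, and the guideline-threshold classification with treatment-gap
#' assessment. Identical configuration and seed give identical artifacts.
#'
#' @param config run configuration from [default_config()] or
#'   [read_config()].
#' @param output_dir directory for artifacts (created if needed); `NULL`
#'   skips writing and only returns results. Defaults to
#'   `config$output_dir`.
#' @return (invisibly) list with `cohort`, `study`, `screening`, `pairs`,
#'   `calibrations` (per reference site, per channel `jackknife_result`s),
#'   `agreement` (per site/channel pre/post `agreement_report`s plus the
#'   independent-set reports), `improvements`, `classification`, and
#'   `summary` (the manifest written to `summary.json`).
#' @export
#' @examples
#' \donttest{
#' cfg <- default_config(cohort = list(n = 6),
#'                       independent = list(n_measurements = 12L,
#'                                          n_participants = 6L))
#' res <- run_pipeline(cfg, output_dir = NULL)
#' res$summary$agreement$aortic$systolic
#' }
run_pipeline <- function(config = default_config(),
                         output_dir = config$output_dir) {
  validate_config(config)
  seed <- config$seed
  device <- do.call(device_model, config$device)

  cohort <- simulate_cohort(config$cohort$n, config$cohort,
                            seed = child_seed(seed, 1))
  study <- simulate_study(cohort, config, device,
                          seed = child_seed(seed, 2))
  screening <- screen_study(
    study$readings,
    systolic_tolerance = config$protocol$bilateral_systolic_tolerance,
    diastolic_tolerance = config$protocol$bilateral_diastolic_tolerance)
  pairs <- assemble_study_pairs(study$readings)

  sites <- c(radial = "radial", aortic = "aortic")
  site_label <- c(radial = "radial", aortic = "aorta")
  calibrations <- list(); agreement <- list(); improvements <- list()
  for (s in names(sites)) {
    cal <- calibrate_pairs(pairs[[s]], family = config$calibration$family,
                           reference_site = site_label[[s]])
    calibrations[[s]] <- cal
    agreement[[s]] <- list(); improvements[[s]] <- list()
    for (ch in c("systolic", "diastolic")) {
      dev_col <- paste0("wrist_", ch); ref_col <- paste0("reference_", ch)
      pre <- bland_altman(data.frame(a = pairs[[s]][[dev_col]],
                                     b = pairs[[s]][[ref_col]]), ch)
      post <- bland_altman(data.frame(a = cal[[ch]]$holdout$calibrated,
                                      b = cal[[ch]]$holdout$reference), ch)
      agreement[[s]][[ch]] <- list(pre = pre, post = post)
      improvements[[s]][[ch]] <- safe_improvement(pre, post)
    }
  }

  # independent archive: wrist vs double-observer auscultatory, before and
  # after applying the deployed aortic calibration to the wrist readings
  indep_agreement <- NULL
  if (!is.null(study$independent)) {
    ind <- study$independent
    wrist <- ind[ind$method == "wrist_cuff", , drop = FALSE]
    ausc <- ind[ind$method == "upper_arm_auscultatory", , drop = FALSE]
    key <- function(x) order(x$patient_id, x$order_index)
    wrist <- wrist[key(wrist), ]; ausc <- ausc[key(ausc), ]
    wrist_cal <- apply_calibration(wrist,
                                   calibrations$aortic$systolic$deployed,
                                   calibrations$aortic$diastolic$deployed)
    indep_agreement <- list()
    for (ch in c("systolic", "diastolic")) {
      pre <- bland_altman(data.frame(a = wrist[[ch]], b = ausc[[ch]]), ch)
      post <- bland_altman(data.frame(a = wrist_cal[[ch]], b = ausc[[ch]]),
                           ch)
      indep_agreement[[ch]] <- list(
        pre = pre, post = post,
        improvement = safe_improvement(pre, post))
    }
  }

  # threshold classification: calibrated wrist and upper arm vs intra-aortic
  aortic_ref <- study$readings[study$readings$method == "intra_aortic", ,
                               drop = FALSE]
  wrist_aortic <- study$readings[study$readings$method == "wrist_cuff" &
                                   study$readings$stage ==
                                     "aortic_simultaneous", , drop = FALSE]
  ord <- function(x) x[order(x$patient_id, x$order_index), , drop = FALSE]
  aortic_ref <- ord(aortic_ref); wrist_aortic <- ord(wrist_aortic)
  wrist_cal <- apply_calibration(wrist_aortic,
                                 calibrations$aortic$systolic$deployed,
                                 calibrations$aortic$diastolic$deployed)
  upper_arm <- ord(simulate_upper_arm_readings(
    study, do.call(device_model, config$upper_arm_device),
    seed = child_seed(seed, 3)))
  th_sets <- lapply(config$thresholds, function(t) {
    threshold_set(t$name, t$systolic, t$diastolic %||% NA_real_)
  })
  classification <- method_comparison(
    list(intra_aortic = aortic_ref, wrist_calibrated = wrist_cal,
         wrist_uncalibrated = wrist_aortic, upper_arm = upper_arm),
    reference_method = "intra_aortic", thresholds = th_sets)

  summary <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("wristcal")),
    n_patients = nrow(cohort),
    hypertension_prevalence = mean(cohort$hypertensive),
    screening_pass_fraction = mean(screening$pass),
    agreement = lapply(agreement, function(site) lapply(site, function(ch) {
      list(pre_amd = ch$pre$absolute_mean_difference,
           pre_sd = ch$pre$sd_absolute,
           post_amd = ch$post$absolute_mean_difference,
           post_sd = ch$post$sd_absolute)
    })),
    improvements = lapply(improvements, function(site) {
      lapply(site, function(x) x[c("accuracy_improvement",
                                   "variability_reduction")])
    }),
    independent = if (!is.null(indep_agreement)) {
      lapply(indep_agreement, function(ch) {
        list(pre_amd = ch$pre$absolute_mean_difference,
             post_amd = ch$post$absolute_mean_difference,
             accuracy_improvement = ch$improvement$accuracy_improvement)
      })
    },
    treatment_gap = stats::setNames(
      lapply(split(classification, classification$threshold_set),
             function(x) as.list(stats::setNames(x$treatment_gap, x$method))),
      unique(sort(classification$threshold_set)))
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(output_dir, f)
    write_readings(study$readings, fp("dataset.csv"))
    if (!is.null(study$independent)) {
      write_readings(study$independent, fp("independent.csv"))
    }
    write.csv(screening, fp("screening.csv"), row.names = FALSE, quote = FALSE)
    write.csv(pairs$radial, fp("pairs_radial.csv"), row.names = FALSE,
              quote = FALSE)
    write.csv(pairs$aortic, fp("pairs_aortic.csv"), row.names = FALSE,
              quote = FALSE)
    write_models(unlist(lapply(calibrations, function(cal) {
      lapply(cal, `[[`, "deployed")
    }), recursive = FALSE), fp("models.csv"))
    rows <- list()
    for (s in names(agreement)) {
      for (ch in names(agreement[[s]])) {
        rows[[length(rows) + 1L]] <-
          agreement_row(agreement[[s]][[ch]]$pre, paste0(s, "_pre"))
        rows[[length(rows) + 1L]] <-
          agreement_row(agreement[[s]][[ch]]$post, paste0(s, "_post"))
      }
    }
    if (!is.null(indep_agreement)) {
      for (ch in names(indep_agreement)) {
        rows[[length(rows) + 1L]] <-
          agreement_row(indep_agreement[[ch]]$pre, "independent_pre")
        rows[[length(rows) + 1L]] <-
          agreement_row(indep_agreement[[ch]]$post, "independent_post")
      }
    }
    write.csv(do.call(rbind, rows), fp("agreement.csv"), row.names = FALSE,
              quote = FALSE)
    write.csv(classification, fp("classification.csv"), row.names = FALSE,
              quote = FALSE)
    config_for_manifest <- config
    jsonlite::write_json(list(summary = summary, config = config_for_manifest),
                         fp("summary.json"), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }

  invisible(list(cohort = cohort, study = study, screening = screening,
                 pairs = pairs, calibrations = calibrations,
                 agreement = agreement, improvements = improvements,
                 independent = indep_agreement,
                 classification = classification, summary = summary))
}
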