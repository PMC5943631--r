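test_that("cohort generator reproduces configured means and is seed-deterministic", {
  big <- simulate_cohort(10000, seed = 42)
  expect_lt(abs(mean(big$mean_aortic_systolic) - 133.4), 1)
  expect_lt(abs(mean(big$mean_aortic_diastolic) - 67.4), 1)
  expect_lt(abs(mean(big$age) - 62.0), 1)
  expect_lt(abs(mean(big$systolic_augmentation) - 12.3), 0.5)
  expect_true(all(big$mean_aortic_systolic >= 96.7 &
                    big$mean_aortic_systolic <= 179.3))
  expect_true(all(big$mean_aortic_systolic > big$mean_aortic_diastolic))
  expect_true(all(big$wrist_circumference >= 15.5 &
                    big$wrist_circumference <= 21.5))

  a <- simulate_cohort(20, seed = 7)
  b <- simulate_cohort(20, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, simulate_cohort(20, seed = 8)))
})

test_that("degenerate cohort config (all SDs zero) yields configured means exactly", {
  cfg <- zero_noise_config()$cohort
  co <- simulate_cohort(5, cfg, seed = 1)
  expect_equal(co$mean_aortic_systolic, rep(133.4, 5))
  expect_equal(co$mean_aortic_diastolic, rep(67.4, 5))
  expect_equal(co$age, rep(62.0, 5))
})

test_that("cohort generator rejects invalid inputs", {
  expect_error(simulate_cohort(0), ">= 1")
  bad <- default_config()$cohort
  bad$aortic_systolic$mean <- 60
  expect_error(simulate_cohort(5, bad), "systolic")
})

test_that("hypertensive flag is stratified to the configured prevalence", {
  co <- simulate_cohort(20, seed = 3)
  expect_identical(sum(co$hypertensive), 15L)
  co2 <- simulate_cohort(40, seed = 4)
  expect_identical(sum(co2$hypertensive), 30L)
})

test_that("beat series has the requested grid and zero-noise limit", {
  p <- simulate_cohort(1, seed = 1)
  s <- simulate_beat_series(p, "aorta", duration = 240, step = 10, seed = 2)
  expect_equal(nrow(s), 25)
  expect_equal(s$time_s, seq(0, 240, by = 10))
  expect_true(all(s$systolic > s$diastolic))

  p0 <- p
  p0$variability_scale_systolic <- 0
  p0$variability_scale_diastolic <- 0
  s0 <- simulate_beat_series(p0, "aorta", 240, 10, seed = 2)
  expect_equal(s0$systolic, rep(p$mean_aortic_systolic, 25))
  expect_equal(s0$diastolic, rep(p$mean_aortic_diastolic, 25))
  sr <- simulate_beat_series(p0, "radial", 240, 10, seed = 2)
  expect_equal(sr$systolic - s0$systolic,
               rep(p$systolic_augmentation, 25))

  expect_error(simulate_beat_series(p, "aorta", duration = 5, step = 10),
               "duration")
  expect_error(simulate_beat_series(p, "femoral"), "arg")
})

test_that("expected 4-minute systolic swing is about 20 mmHg (Monte Carlo)", {
  p <- simulate_cohort(1, seed = 1)
  set.seed(11)
  rngs <- replicate(1000, {
    s <- simulate_beat_series(p, "aorta", 240, 10)
    c(diff(range(s$systolic)), diff(range(s$diastolic)))
  })
  expect_lt(abs(mean(rngs[1, ]) - 20), 3)
  expect_lt(abs(mean(rngs[2, ]) - 10), 1.5)
})

test_that("oscillometric envelope peaks at MAP with bounded support", {
  w <- constant_window(120, 80)
  env <- oscillometric_envelope(w)
  map <- 80 + 40 / 3
  expect_lt(abs(env$pressure[which.max(env$amplitude)] - map), 0.51)
  # closed form for constant beats: Gaussian kernel of width PP/2, clipped
  inside <- env$pressure >= 60 & env$pressure <= 140
  expect_equal(env$amplitude[inside],
               exp(-(env$pressure[inside] - map)^2 / (2 * 20^2)))
  expect_true(all(env$amplitude[env$pressure < 60] == 0))
  expect_true(all(env$amplitude[env$pressure > 140] == 0))
  expect_error(oscillometric_envelope(w, list(from = 90, to = 200, by = 1)),
               "span")
})

test_that("fixed-ratio estimate inverts the analytic triangular envelope", {
  grid <- seq(60, 140, by = 1)
  tri <- data.frame(pressure = grid, amplitude = 1 - abs(grid - 100) / 40)
  est <- fixed_ratio_estimate(tri, c(0.55, 0.85))
  expect_equal(est$systolic, 118, tolerance = 1e-9)
  expect_equal(est$diastolic, 94, tolerance = 1e-9)
  expect_equal(est$map, 100)

  # degenerate ratios collapse onto the peak
  est1 <- fixed_ratio_estimate(tri, c(1, 1))
  expect_equal(est1$systolic, 100)
  expect_equal(est1$diastolic, 100)

  # symmetric envelope: crossings are mirror images about the peak
  for (r in c(0.3, 0.6, 0.9)) {
    e <- fixed_ratio_estimate(tri, c(r, r))
    expect_equal(e$systolic - e$map, e$map - e$diastolic, tolerance = 1e-9)
  }

  mono <- data.frame(pressure = grid, amplitude = seq_along(grid))
  expect_error(fixed_ratio_estimate(mono), "interior peak")
  # an envelope that never falls to the ratio level within the grid
  shallow <- data.frame(pressure = grid, amplitude = 1 - abs(grid - 100) / 200)
  expect_error(fixed_ratio_estimate(shallow, c(0.55, 0.85)), "outside")
})

test_that("device reading applies the affine model and propagates uncertainty", {
  w <- constant_window(120, 80)
  identity <- device_model(0, 1, 0, 1, 0, 0)
  r <- device_reading(w, identity, seed = 1)
  expect_equal(r$systolic, 120)
  expect_equal(r$diastolic, 80)
  expect_equal(r$sd_systolic, 0)
  expect_identical(r$method, "wrist_cuff")

  shift <- device_model(10, 1, 0, 1, 0, 0)
  expect_equal(device_reading(w, shift, seed = 1)$systolic, 130)

  # reported SD combines device gain x beat variance with noise in quadrature
  wv <- data.frame(time_s = 0:6 * 10,
                   systolic = c(118, 125, 122, 116, 121, 124, 119),
                   diastolic = rep(80, 7))
  m <- device_model(0, 0.9, 0, 1, 4, 0)
  r2 <- device_reading(wv, m, seed = 1)
  expect_equal(r2$sd_systolic, sqrt(0.9^2 * var(wv$systolic) + 16))
  expect_error(device_reading(wv[0, ], m), "empty")
})

test_that("replicate device readings scatter like the reported SD", {
  w <- constant_window(120, 80)
  m <- device_model(0, 1, 0, 1, 6, 4)
  set.seed(5)
  reps <- vapply(1:10000, function(i) device_reading(w, m)$systolic,
                 numeric(1))
  reported <- device_reading(w, m, seed = 1)$sd_systolic
  expect_lt(abs(sd(reps) - reported) / reported, 0.05)
})

test_that("auscultatory readings follow the terminal-digit rounding convention", {
  w <- constant_window(121, 79)
  obs0 <- list(noise_sd_systolic = 0, noise_sd_diastolic = 0,
               rounding_unit = 2, n_observers = 1L)
  r <- auscultatory_reading(w, obs0, seed = 1)
  expect_equal(r$systolic, 122) # half rounded away from zero
  expect_equal(r$diastolic, 80)
  expect_true(is.na(r$sd_systolic))

  obs2 <- modifyList(obs0, list(n_observers = 2L))
  r2 <- auscultatory_reading(w, obs2, seed = 1)
  expect_equal(r2$systolic, 122) # both observers identical at zero noise

  set.seed(9)
  obs <- list(noise_sd_systolic = 4, noise_sd_diastolic = 0,
              rounding_unit = 2, n_observers = 1L)
  reps <- vapply(1:5000, function(i) auscultatory_reading(w, obs)$systolic,
                 numeric(1))
  expect_lt(abs(sd(reps) - 4) / 4, 0.10)
})

test_that("study schedule produces 10 Day-2 readings per patient", {
  cohort <- simulate_cohort(20, seed = 1)
  cfg <- default_config(independent = list(n_measurements = 0L))
  study <- simulate_study(cohort, cfg, seed = 2)
  day2 <- study$readings[study$readings$stage %in%
                           c("conditioning", "radial_simultaneous",
                             "aortic_simultaneous"), ]
  counts <- table(day2$patient_id)
  expect_true(all(counts == 10))
  expect_equal(sum(day2$method == "wrist_cuff"), 20 * 6)
  aortic_pairs <- day2[day2$stage == "aortic_simultaneous" &
                         day2$method == "wrist_cuff", ]
  expect_equal(nrow(aortic_pairs), 40)
  expect_true(all(study$readings$systolic > study$readings$diastolic))
})

test_that("study generation is deterministic and independent set has the configured shape", {
  cohort <- simulate_cohort(5, seed = 1)
  cfg <- default_config(independent = list(n_measurements = 20L,
                                           n_participants = 7L))
  s1 <- simulate_study(cohort, cfg, seed = 3)
  s2 <- simulate_study(cohort, cfg, seed = 3)
  expect_identical(s1$readings, s2$readings)
  expect_identical(s1$independent, s2$independent)
  expect_equal(nrow(s1$independent), 40) # 20 wrist + 20 auscultatory
  expect_equal(length(unique(s1$independent$patient_id)), 7)
})

test_that("zero-noise identity study: wrist equals reference up to augmentation", {
  cfg <- zero_noise_config()
  cohort <- simulate_cohort(2, cfg$cohort, seed = 1)
  study <- simulate_study(cohort, cfg, seed = 2)
  r <- study$readings
  wr <- r[r$method == "wrist_cuff" & r$stage == "radial_simultaneous", ]
  rad <- r[r$method == "intra_radial", ]
  expect_equal(wr$systolic, rad$systolic)
  expect_equal(wr$diastolic, rad$diastolic)
  wa <- r[r$method == "wrist_cuff" & r$stage == "aortic_simultaneous", ]
  ao <- r[r$method == "intra_aortic", ]
  expect_equal(wa$systolic - ao$systolic,
               rep(cohort$systolic_augmentation, each = 2))
  expect_equal(wa$diastolic - ao$diastolic,
               rep(cohort$diastolic_augmentation, each = 2))
})
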