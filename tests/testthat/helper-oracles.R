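# Independent brute-force oracles, deliberately written without reusing any
# package internals.

# OLS via explicit normal equations
oracle_ols <- function(device, reference) {
  n <- length(device)
  sxx <- sum(device^2) - sum(device)^2 / n
  sxy <- sum(device * reference) - sum(device) * sum(reference) / n
  slope <- sxy / sxx
  intercept <- mean(reference) - slope * mean(device)
  c(intercept = intercept, slope = slope)
}

# leave-one-out jackknife, refit from scratch with oracle_ols each time
oracle_jackknife <- function(device, reference) {
  n <- length(device)
  vapply(seq_len(n), function(i) {
    cf <- oracle_ols(device[-i], reference[-i])
    cf[["intercept"]] + cf[["slope"]] * device[i]
  }, numeric(1))
}

# one-tailed Fisher exact by full enumeration of all 2x2 tables with the
# observed margins, probabilities from choose()
oracle_fisher <- function(a, b, c, d, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  m <- a + b; nn <- c + d; k <- a + c
  if (m == 0 || nn == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - nn):min(k, m)
  probs <- vapply(support, function(x) {
    choose(m, x) * choose(nn, k - x) / choose(m + nn, k)
  }, numeric(1))
  keep <- if (alternative == "greater") support >= a else support <= a
  sum(probs[keep])
}

# Population least-squares calibration coefficients for the radial-reference
# path, derived analytically from the generator and device parameters. The
# reference value per reading is the radial beat-window mean r; the device
# value is dev = alpha + beta * r + eps. The OLS of reference on device
# converges to slope* = beta V / (beta^2 V + sigma_eps^2) with
# V = Var(r) = (truncated patient pressure variance) + (augmentation
# variance) + (AR(1) window-mean variance), and
# intercept* = mu_ref - slope* (alpha + beta mu_ref).
oracle_population_calibration <- function(config, channel) {
  trunc_var <- function(mean, sd, lo, hi) {
    tm <- function(mu) {
      a <- (lo - mu) / sd; b <- (hi - mu) / sd
      z <- pnorm(b) - pnorm(a)
      mu + sd * (dnorm(a) - dnorm(b)) / z
    }
    mu <- uniroot(function(m) tm(m) - mean, c(mean - 6 * sd, mean + 6 * sd))$root
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    z <- pnorm(b) - pnorm(a)
    sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
              ((dnorm(a) - dnorm(b)) / z)^2)
  }
  co <- config$cohort; bc <- config$beats; dv <- config$device
  phi <- bc$lag1_correlation
  m <- length(seq(0, bc$window_duration, by = bc$window_step))
  win_factor <- sum(phi^abs(outer(seq_len(m), seq_len(m), "-"))) / m^2
  if (channel == "systolic") {
    pr <- co$aortic_systolic; aug <- co$systolic_augmentation
    scale <- bc$variability_scale_systolic
    beta <- dv$slope_systolic; alpha <- dv$intercept_systolic
    se <- dv$noise_sd_systolic
  } else {
    pr <- co$aortic_diastolic; aug <- co$diastolic_augmentation
    scale <- bc$variability_scale_diastolic
    beta <- dv$slope_diastolic; alpha <- dv$intercept_diastolic
    se <- dv$noise_sd_diastolic
  }
  v <- trunc_var(pr$mean, pr$sd, pr$min, pr$max) + aug$sd^2 +
    scale^2 * win_factor
  mu_ref <- pr$mean + aug$mean
  slope <- beta * v / (beta^2 * v + se^2)
  c(slope = slope, intercept = mu_ref - slope * (alpha + beta * mu_ref))
}

# constant beat window at the given pressures
constant_window <- function(systolic = 120, diastolic = 80, n = 7) {
  data.frame(time_s = seq(0, by = 10, length.out = n),
             systolic = rep(systolic, n), diastolic = rep(diastolic, n))
}

# small cohort config with zeroed randomness for noise-free limits
zero_noise_config <- function(n = 2L) {
  default_config(
    cohort = list(
      n = n,
      age = list(sd = 0), bmi = list(sd = 0),
      wrist_circumference = list(sd = 0),
      aortic_systolic = list(sd = 0), aortic_diastolic = list(sd = 0),
      systolic_augmentation = list(sd = 0),
      diastolic_augmentation = list(sd = 0)
    ),
    beats = list(variability_scale_systolic = 0,
                 variability_scale_diastolic = 0),
    device = list(intercept_systolic = 0, slope_systolic = 1,
                  noise_sd_systolic = 0, intercept_diastolic = 0,
                  slope_diastolic = 1, noise_sd_diastolic = 0),
    observer = list(noise_sd_systolic = 0, noise_sd_diastolic = 0),
    independent = list(n_measurements = 0L)
  )
}
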