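#' Configuration for a synthetic wearable cohort
#'
#' Bundles every knob of the synthetic cohort generator. The defaults emulate
#' a free-living smartwatch protocol: step rate recorded once per minute,
#' heart rate every 5 seconds, activity bouts of walking/running between
#' 06:00 and 23:00, sleep (zero steps) from 23:00 to 06:00, and wrist-sensor
#' error figures reported for consumer PPG devices (step undercount around
#' -3%, per-sample heart-rate MAPE around 11%).
#'
#' `couple_fraction` is the proportion of scheduled bout minutes whose
#' underlying step rate is forced to equal the noiseless minute-mean heart
#' rate (1:1 entrainment) before sensor noise is applied. Entrainment
#' probability is weighted by bout duration (longer activities entrain more,
#' minute-level probability proportional to the bout's length, normalised so
#' the expected overall fraction equals `couple_fraction`), reflecting that
#' sustained locomotion is where frequency locking emerges.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param days recording days per subject.
#' @param seed root integer seed; subject `i` uses `seed + i` so subjects are
#'   independent and individually reproducible.
#' @param resting_hr_range beats/min interval from which each subject's
#'   resting heart rate is drawn.
#' @param bout_rate mean number of scheduled activity bouts per day.
#' @param bout_duration_mean,bout_duration_sd minutes; bout durations are
#'   normal with these moments, truncated to `[10, 180]`.
#' @param cadence_range steps/min interval for per-bout cadence; must lie
#'   within `[60, 200]`.
#' @param couple_fraction proportion of bout minutes forced to entrainment,
#'   in `[0, 1]`.
#' @param hr_noise_mape target mean absolute percentage error of emitted
#'   5-second heart-rate samples (multiplicative Gaussian noise with
#'   `sd = hr_noise_mape * sqrt(pi/2)`).
#' @param sr_bias proportional step-rate sensor bias (negative = undercount).
#' @param sr_jitter_sd steps/min standard deviation of additive step-rate
#'   sensor jitter.
#' @param hr_sample_period seconds between heart-rate samples; must divide 60.
#' @return an object of class `clc_cohort_config` (a named list).
#' @examples
#' cohort_config(n_subjects = 2, days = 7, seed = 1)
#' @export
cohort_config <- function(n_subjects = 16,
                          days = 150,
                          seed = 1,
                          resting_hr_range = c(47, 70),
                          bout_rate = 3,
                          bout_duration_mean = 60,
                          bout_duration_sd = 30,
                          cadence_range = c(60, 180),
                          couple_fraction = 0.05,
                          hr_noise_mape = 0.11,
                          sr_bias = -0.03,
                          sr_jitter_sd = 2,
                          hr_sample_period = 5) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    days = as.integer(days),
    seed = as.integer(seed),
    resting_hr_range = as.numeric(resting_hr_range),
    bout_rate = as.numeric(bout_rate),
    bout_duration_mean = as.numeric(bout_duration_mean),
    bout_duration_sd = as.numeric(bout_duration_sd),
    cadence_range = as.numeric(cadence_range),
    couple_fraction = as.numeric(couple_fraction),
    hr_noise_mape = as.numeric(hr_noise_mape),
    sr_bias = as.numeric(sr_bias),
    sr_jitter_sd = as.numeric(sr_jitter_sd),
    hr_sample_period = as.integer(hr_sample_period)
  )
  class(cfg) <- "clc_cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_subjects <= 0L) abort("`n_subjects` must be positive")
  if (cfg$days <= 0L) abort("`days` must be positive")
  if (is.na(cfg$seed)) abort("`seed` must be an integer")
  if (length(cfg$resting_hr_range) != 2 || diff(cfg$resting_hr_range) < 0) {
    abort("`resting_hr_range` must be an increasing interval")
  }
  if (cfg$couple_fraction < 0 || cfg$couple_fraction > 1) {
    abort("`couple_fraction` must lie in [0, 1]")
  }
  if (length(cfg$cadence_range) != 2 || diff(cfg$cadence_range) < 0 ||
    cfg$cadence_range[1] < 60 || cfg$cadence_range[2] > 200) {
    abort("`cadence_range` must be an interval within [60, 200] steps/min")
  }
  if (cfg$hr_sample_period <= 0L || 60L %% cfg$hr_sample_period != 0L) {
    abort("`hr_sample_period` must divide 60 seconds")
  }
  if (cfg$hr_noise_mape < 0 || cfg$sr_jitter_sd < 0) {
    abort("noise magnitudes must be non-negative")
  }
  invisible(cfg)
}

#' @export
print.clc_cohort_config <- function(x, ...) {
  cat("<clc_cohort_config>\n")
  cat(sprintf(
    "  %d subjects x %d days, seed %d\n", x$n_subjects, x$days, x$seed
  ))
  cat(sprintf(
    "  couple_fraction %.3f, cadence %g-%g steps/min, bouts %.1f/day (%.0f +/- %.0f min)\n",
    x$couple_fraction, x$cadence_range[1], x$cadence_range[2],
    x$bout_rate, x$bout_duration_mean, x$bout_duration_sd
  ))
  cat(sprintf(
    "  sensor: HR MAPE %.0f%% @ %ds, SR bias %+.0f%%, SR jitter %.1f steps/min\n",
    100 * x$hr_noise_mape, x$hr_sample_period, 100 * x$sr_bias, x$sr_jitter_sd
  ))
  invisible(x)
}
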