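# Synthetic cohort generator: seeded wearable streams with ground truth.

# Fixed schedule/physiology constants (documented in the methods vignette).
.GEN <- list(
  origin = "2019-11-01",          # first recording day
  sleep_start_min = 1380L,        # 23:00, steps forced to zero
  sleep_end_min = 360L,           # 06:00
  bout_separation = 90L,          # min gap between scheduled bouts (minutes)
  bout_duration_clip = c(10, 180),
  hr_elevation_range = c(20, 110), # bout HR elevation over resting, beats/min
  hr_tau = 2,                     # first-order HR response time constant, min
  hr_sleep_drop = 5,              # beats/min below resting while asleep
  hr_rest_rise = 5,               # beats/min above resting awake at rest
  cadence_ar_phi = 0.85,          # within-bout cadence wander AR(1)
  cadence_ar_sd = 4,
  cadence_white_sd = 2,
  hr_ar_phi = 0.9,                # within-bout HR-target wander AR(1)
  hr_ar_sd = 2.5,
  rest_sr_lambda = 6              # Poisson mean of resting step counts
)

# Duration-weighted per-minute entrainment probabilities p_i = min(1, c*w_i),
# with c chosen by bisection so that mean(p) equals the requested fraction
# (capping at 1 is redistributed, so couple_fraction = 1 entrains everything).
entrain_probs <- function(w, fraction) {
  if (fraction >= 1) return(rep(1, length(w)))
  lo <- 0
  hi <- 1 / min(w) # all probabilities capped at 1 -> mean 1 >= fraction
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (mean(pmin(1, mid * w)) < fraction) lo <- mid else hi <- mid
  }
  pmin(1, hi * w)
}

ar1 <- function(n, phi, sd) {
  if (n == 0L) return(numeric(0))
  as.numeric(stats::filter(rnorm(n, 0, sd), phi, method = "recursive"))
}

#' Generate one subject's synthetic wearable streams
#'
#' Simulates a subject minute-by-minute: activity bouts are scheduled between
#' 06:00 and 23:00 with at least 90 minutes between them (so downstream bout
#' segmentation at a 60-minute gap recovers the schedule); within a bout the
#' true step rate wanders around the bout cadence; the true heart rate relaxes
#' with a ~2-minute time constant towards a per-bout target drawn
#' independently of cadence. Minutes flagged as entrained have their true
#' step rate set equal to the noiseless minute-mean heart rate before any
#' sensor noise. Heart rate is emitted as integer 5-second samples with
#' multiplicative noise; step rate as per-minute integers after proportional
#' bias and additive jitter.
#'
#' The per-bout heart-rate elevation is drawn independently of the bout
#' cadence, so with `couple_fraction = 0` the post-filter heart-rate and
#' step-rate values of a subject are statistically independent and the
#' random-pairing null distribution is calibrated by construction.
#'
#' @param config a [cohort_config()].
#' @param subject_index positive integer; the subject's RNG stream is
#'   `config$seed + subject_index`.
#' @return A list of class `clc_subject_streams` with elements
#'   `heart_rate` (tibble: `timestamp`, `bpm`), `steps` (tibble: `timestamp`,
#'   `steps`), and `truth` (list with per-minute tibble `minutes` and
#'   per-bout tibble `bouts`), plus `subject_id` and `seed`.
#' @examples
#' s <- generate_subject(cohort_config(n_subjects = 1, days = 2, seed = 7), 1)
#' head(s$steps)
#' @export
generate_subject <- function(config, subject_index) {
  validate_cohort_config(config)
  stopifnot(subject_index >= 1)
  seed_s <- subject_seed(config$seed, subject_index)

  withr::with_seed(seed_s, {
    n_min <- config$days * 1440L
    minute_of_day <- seq_len(n_min) - 1L
    t0 <- as.POSIXct(.GEN$origin, tz = "UTC")
    timestamp <- t0 + 60 * (seq_len(n_min) - 1L)
    mod <- minute_of_day %% 1440L
    asleep <- mod >= .GEN$sleep_start_min | mod < .GEN$sleep_end_min

    r0 <- runif(1, config$resting_hr_range[1], config$resting_hr_range[2])

    sched <- schedule_bouts(config)
    n_bouts <- nrow(sched)

    bout_id <- rep(NA_integer_, n_min)
    if (n_bouts > 0) {
      idx <- sequence(sched$duration, from = sched$start_min + 1L)
      bout_id[idx] <- rep.int(seq_len(n_bouts), sched$duration)
    }
    in_bout <- !is.na(bout_id)

    # true step rate -------------------------------------------------------
    sr_true <- numeric(n_min)
    rest <- !asleep & !in_bout
    sr_true[rest] <- pmin(rpois(sum(rest), .GEN$rest_sr_lambda), 59)
    if (n_bouts > 0) {
      wander <- unlist(lapply(
        sched$duration,
        function(d) ar1(d, .GEN$cadence_ar_phi, .GEN$cadence_ar_sd)
      ), use.names = FALSE)
      sr_true[in_bout] <- sched$cadence[bout_id[in_bout]] + wander +
        rnorm(sum(in_bout), 0, .GEN$cadence_white_sd)
      sr_true[in_bout] <- pmax(sr_true[in_bout], 0)
    }

    # true heart rate ------------------------------------------------------
    target <- rep(r0 + .GEN$hr_rest_rise, n_min)
    target[asleep] <- r0 - .GEN$hr_sleep_drop
    if (n_bouts > 0) {
      hr_wander <- unlist(lapply(
        sched$duration,
        function(d) ar1(d, .GEN$hr_ar_phi, .GEN$hr_ar_sd)
      ), use.names = FALSE)
      target[in_bout] <- r0 + sched$hr_elevation[bout_id[in_bout]] + hr_wander
    }
    alpha <- 1 - exp(-1 / .GEN$hr_tau)
    hr_true <- as.numeric(stats::filter(alpha * target, 1 - alpha,
      method = "recursive", init = r0
    ))

    # entrainment ----------------------------------------------------------
    entrained <- rep(FALSE, n_min)
    if (n_bouts > 0 && config$couple_fraction > 0) {
      w <- sched$duration[bout_id[in_bout]]
      p <- entrain_probs(w, config$couple_fraction)
      entrained[in_bout] <- runif(sum(in_bout)) < p
      sr_true[entrained] <- hr_true[entrained]
    }

    # emission: step file --------------------------------------------------
    jitter <- numeric(n_min)
    nz <- sr_true > 0
    if (config$sr_jitter_sd > 0) {
      jitter[nz] <- rnorm(sum(nz), 0, config$sr_jitter_sd)
    }
    sr_emit <- as.integer(pmin(
      round(pmax(0, (sr_true + jitter) * (1 + config$sr_bias))), 300
    ))
    sr_emit[asleep] <- 0L

    # emission: heart-rate samples -----------------------------------------
    spm <- 60L %/% config$hr_sample_period
    n_samp <- n_min * spm
    eps <- if (config$hr_noise_mape > 0) {
      rnorm(n_samp, 0, config$hr_noise_mape * sqrt(pi / 2))
    } else {
      numeric(n_samp)
    }
    bpm <- as.integer(round(rep(hr_true, each = spm) * (1 + eps)))
    hr_ts <- rep(timestamp, each = spm) +
      rep(config$hr_sample_period * (seq_len(spm) - 1L), times = n_min)

    truth_minutes <- tibble(
      timestamp = timestamp,
      in_bout = in_bout,
      bout_id = bout_id,
      entrained = entrained,
      scheduled_cadence = ifelse(in_bout, sched$cadence[bout_id], NA_real_),
      true_sr = sr_true,
      true_hr = hr_true,
      emitted_sr = sr_emit
    )
    truth_bouts <- tibble(
      bout_id = seq_len(n_bouts),
      start = timestamp[sched$start_min + 1L],
      end = timestamp[sched$start_min + sched$duration],
      duration = sched$duration,
      cadence = sched$cadence,
      intensity_class = intensity_class_of(sched$cadence),
      hr_target = r0 + sched$hr_elevation,
      n_entrained = as.integer(tabulate(bout_id[entrained], nbins = n_bouts))
    )

    structure(
      list(
        subject_id = sprintf("S%02d", subject_index),
        seed = seed_s,
        resting_hr = r0,
        config = config,
        heart_rate = tibble(timestamp = hr_ts, bpm = bpm),
        steps = tibble(timestamp = timestamp, steps = sr_emit),
        truth = list(minutes = truth_minutes, bouts = truth_bouts)
      ),
      class = "clc_subject_streams"
    )
  })
}

# Schedule non-overlapping bouts for the whole recording, day by day.
# Returns a data frame with start_min (0-based minute index into the whole
# recording), duration (minutes), cadence, hr_elevation.
schedule_bouts <- function(config) {
  out <- vector("list", config$days)
  for (d in seq_len(config$days)) {
    nb <- rpois(1, config$bout_rate)
    if (nb == 0) {
      out[[d]] <- NULL
      next
    }
    dur <- round(rnorm(nb, config$bout_duration_mean, config$bout_duration_sd))
    dur <- pmin(pmax(dur, .GEN$bout_duration_clip[1]), .GEN$bout_duration_clip[2])
    start <- floor(runif(nb, .GEN$sleep_end_min, .GEN$sleep_start_min - dur))
    ord <- order(start)
    start <- start[ord]
    dur <- dur[ord]
    keep <- logical(nb)
    prev_end <- -Inf
    for (i in seq_len(nb)) {
      if (start[i] >= prev_end + .GEN$bout_separation) {
        keep[i] <- TRUE
        prev_end <- start[i] + dur[i]
      }
    }
    if (!any(keep)) {
      out[[d]] <- NULL
      next
    }
    out[[d]] <- data.frame(
      start_min = (d - 1L) * 1440L + as.integer(start[keep]),
      duration = as.integer(dur[keep])
    )
  }
  sched <- do.call(rbind, out)
  if (is.null(sched) || nrow(sched) == 0) {
    return(data.frame(
      start_min = integer(0), duration = integer(0),
      cadence = numeric(0), hr_elevation = numeric(0)
    ))
  }
  nb <- nrow(sched)
  sched$cadence <- runif(nb, config$cadence_range[1], config$cadence_range[2])
  sched$hr_elevation <- runif(nb, .GEN$hr_elevation_range[1], .GEN$hr_elevation_range[2])
  sched
}

#' @export
print.clc_subject_streams <- function(x, ...) {
  cat(sprintf(
    "<clc_subject_streams> %s: %d HR samples, %d step minutes, %d bouts, %d entrained minutes\n",
    x$subject_id, nrow(x$heart_rate), nrow(x$steps),
    nrow(x$truth$bouts), sum(x$truth$minutes$entrained)
  ))
  invisible(x)
}
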