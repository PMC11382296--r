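# Per-subject and cohort orchestration of the full pipeline.

#' Analysis configuration
#'
#' Every threshold of the pipeline in one place: the activity filter, the
#' coupling deviation bands, the cadence intensity cuts, the bout gap, the
#' grouping cutoff, the null-model method and the histogram grid.
#'
#' @param dialect raw-file dialect for file-based inputs.
#' @param sr_threshold steps/min activity filter (minutes strictly below are
#'   excluded).
#' @param min_hr_samples minimum heart-rate samples per minute.
#' @param clc_threshold,weak_threshold coupling deviation bands.
#' @param intensity_cuts cadence cuts for light/moderate/vigorous.
#' @param gap minutes; bout split threshold.
#' @param d_cutoff percentage points; moderate-vs-vigorous grouping cutoff.
#' @param null_method `"exact"` or `"sampled"`.
#' @param n_samples Monte Carlo pairs when `null_method = "sampled"`.
#' @param seed seed for the sampled null.
#' @param age_split years; cohort age-group boundary.
#' @return a named list of class `clc_analysis_config`.
#' @export
analysis_config <- function(dialect = c("csv", "fitbit-json"),
                            sr_threshold = 60,
                            min_hr_samples = 6,
                            clc_threshold = 0.01,
                            weak_threshold = 0.10,
                            intensity_cuts = c(60, 100, 130),
                            gap = 60,
                            d_cutoff = 1.5,
                            null_method = c("exact", "sampled"),
                            n_samples = 1e5,
                            seed = 1,
                            age_split = 40) {
  structure(
    list(
      dialect = match.arg(dialect),
      sr_threshold = sr_threshold,
      min_hr_samples = min_hr_samples,
      clc_threshold = clc_threshold,
      weak_threshold = weak_threshold,
      intensity_cuts = intensity_cuts,
      gap = gap,
      d_cutoff = d_cutoff,
      null_method = match.arg(null_method),
      n_samples = n_samples,
      seed = seed,
      age_split = age_split
    ),
    class = "clc_analysis_config"
  )
}

empty_subject_report <- function(subject_id, note) {
  structure(
    list(
      subject_id = subject_id, empty = TRUE, note = note,
      summary = tibble(subject_id = subject_id, n_instances = 0L),
      tables = list()
    ),
    class = "clc_subject_report"
  )
}

#' Run the full pipeline for one subject
#'
#' Reads (or takes) the raw streams, averages heart rate to minutes,
#' synchronises and filters, classifies coupling and intensity, segments
#' bouts, computes occurrence summaries, the grouping statistic, the exact
#' (or sampled) random-pairing null, and the observed-vs-null comparison.
#'
#' @param heart_rate,steps file paths, or tibbles as returned by
#'   [read_heart_rate()] / [read_steps()] (columns `timestamp`+`bpm` and
#'   `timestamp`+`steps`).
#' @param config an [analysis_config()].
#' @param subject_id label used in the report.
#' @return object of class `clc_subject_report`: `$summary` (one-row tibble)
#'   and `$tables` (instances, bouts, occurrence, occurrence_by_intensity,
#'   durations, null/observed summaries, comparison). Subjects with zero
#'   post-filter minutes yield a flagged empty report.
#' @export
run_subject <- function(heart_rate, steps, config = analysis_config(),
                        subject_id = "subject") {
  if (is.character(heart_rate)) {
    heart_rate <- read_heart_rate(heart_rate, config$dialect)
  }
  if (is.character(steps)) {
    steps <- read_steps(steps, config$dialect)
  }
  if (nrow(heart_rate) == 0 || nrow(steps) == 0) {
    warn(sprintf("%s: empty input stream; flagged empty report", subject_id))
    return(empty_subject_report(subject_id, "empty input stream"))
  }
  hr_minutes <- minutely_hr(heart_rate, config$min_hr_samples)
  aligned <- suppressWarnings(
    align_and_filter(hr_minutes, steps, config$sr_threshold)
  )
  if (nrow(aligned) < 2) {
    warn(sprintf("%s: no post-filter minutes; flagged empty report", subject_id))
    return(empty_subject_report(subject_id, "no post-filter minutes"))
  }

  instances <- classify_coupling(
    aligned, config$clc_threshold, config$weak_threshold, config$intensity_cuts
  )
  occ <- occurrence(instances)
  occ_int <- occurrence(instances, by_intensity = TRUE)
  bouts <- segment_bouts(instances, config$gap)
  durations <- bout_duration_by_class(bouts)

  occ_pct <- setNames(occ$percentage, as.character(occ$coupling_class))
  clc_by_int <- occ_int |>
    filter(.data$coupling_class == "CLC")
  clc_int_pct <- setNames(
    clc_by_int$percentage, as.character(clc_by_int$intensity_class)
  )
  int_n <- occ_int |>
    summarise(n = sum(.data$n), .by = "intensity_class")
  int_share <- setNames(
    100 * int_n$n / sum(int_n$n), as.character(int_n$intensity_class)
  )
  grouping <- group_subject(
    if (int_n$n[int_n$intensity_class == "moderate"] > 0) clc_int_pct[["moderate"]] else NA_real_,
    if (int_n$n[int_n$intensity_class == "vigorous"] > 0) clc_int_pct[["vigorous"]] else NA_real_,
    config$d_cutoff
  )

  null <- if (config$null_method == "exact") {
    null_exact(instances$hr, instances$sr,
      clc_threshold = config$clc_threshold,
      weak_threshold = config$weak_threshold
    )
  } else {
    null_sampled(instances$hr, instances$sr,
      n_samples = config$n_samples, seed = config$seed,
      clc_threshold = config$clc_threshold,
      weak_threshold = config$weak_threshold
    )
  }
  observed <- observed_distribution(instances,
    clc_threshold = config$clc_threshold,
    weak_threshold = config$weak_threshold
  )
  comparison <- compare_distributions(observed, null)
  pearson <- pearson_correlation(instances$hr, instances$sr)

  # resting heart rate: minute HR outside activity (sr below the filter or
  # no step record)
  resting <- hr_minutes |>
    left_join(
      tibble(
        timestamp = floor_minute(steps$timestamp),
        sr = as.numeric(steps$steps)
      ),
      by = "timestamp"
    ) |>
    filter(is.na(.data$sr) | .data$sr < config$sr_threshold)

  dur_pct <- function(cls) {
    i <- match(cls, as.character(durations$bout_class))
    if (is.na(i)) NA_real_ else durations$median_duration[i]
  }

  summary <- tibble(
    subject_id = subject_id,
    n_minutes = nrow(hr_minutes),
    n_instances = nrow(instances),
    n_bouts = nrow(bouts),
    resting_hr_median = median(resting$hr),
    resting_hr_iqr = iqr_of(resting$hr),
    r_median = median(instances$ratio),
    r_iqr = iqr_of(instances$ratio),
    clc_pct = occ_pct[["CLC"]],
    weak_clc_pct = occ_pct[["weak_CLC"]],
    no_clc_pct = occ_pct[["no_CLC"]],
    clc_light_pct = clc_int_pct[["light"]],
    clc_moderate_pct = clc_int_pct[["moderate"]],
    clc_vigorous_pct = clc_int_pct[["vigorous"]],
    light_share_pct = int_share[["light"]],
    moderate_share_pct = int_share[["moderate"]],
    vigorous_share_pct = int_share[["vigorous"]],
    d_statistic = grouping$d_statistic,
    group = grouping$group,
    pearson_r = pearson$effect_size,
    pearson_p = pearson$p_value,
    observed_p_clc = observed$p_clc,
    observed_p_weak_or_clc = observed$p_weak_or_clc,
    null_p_clc = null$p_clc,
    null_p_weak_or_clc = null$p_weak_or_clc,
    delta_p = comparison$delta_p,
    ks_statistic = comparison$ks_statistic,
    ks_p = comparison$ks_p,
    observed_median_r = observed$median,
    observed_iqr = observed$iqr,
    observed_skewness = observed$skewness,
    null_median_r = null$median,
    null_iqr = null$iqr,
    null_skewness = null$skewness,
    duration_median_clc = dur_pct("CLC"),
    duration_median_weak = dur_pct("weak_CLC"),
    duration_median_no = dur_pct("no_CLC")
  )

  structure(
    list(
      subject_id = subject_id, empty = FALSE, note = NA_character_,
      summary = summary,
      tables = list(
        instances = instances,
        bouts = bouts,
        occurrence = occ,
        occurrence_by_intensity = occ_int,
        durations = durations,
        observed = observed,
        null = null,
        comparison = comparison
      ),
      config = config
    ),
    class = "clc_subject_report"
  )
}

#' @export
print.clc_subject_report <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("<clc_subject_report> %s: EMPTY (%s)\n", x$subject_id, x$note))
    return(invisible(x))
  }
  s <- x$summary
  cat(sprintf(
    "<clc_subject_report> %s: %d active minutes, median R %.3f, CLC %.2f%%, weak %.2f%%, null p_clc %.3f\n",
    x$subject_id, s$n_instances, s$r_median, s$clc_pct, s$weak_clc_pct,
    s$null_p_clc
  ))
  invisible(x)
}

#' @method tidy clc_subject_report
#' @export
tidy.clc_subject_report <- function(x, ...) x$summary

#' @method glance clc_subject_report
#' @export
glance.clc_subject_report <- function(x, ...) {
  x$summary[, c(
    "subject_id", "n_instances", "r_median", "clc_pct", "weak_clc_pct",
    "pearson_r", "d_statistic", "group", "delta_p", "ks_p"
  )]
}
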