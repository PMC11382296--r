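# Coupling ratio, coupling/intensity classification, occurrence summaries,
# activity-bout segmentation and the moderate-vs-vigorous grouping statistic.

#' Classify aligned minutes by coupling strength and activity intensity
#'
#' For each aligned active minute the coupling ratio `R = sr / hr` and its
#' deviation from 1:1 locking, `|R - 1|`, are computed. Coupling classes:
#' `CLC` (deviation <= `clc_threshold`, default 1%), `weak_CLC`
#' (`clc_threshold` < deviation <= `weak_threshold`, default 10%), `no_CLC`
#' otherwise. Intensity classes use left-closed cadence bands:
#' light `[60, 100)`, moderate `[100, 130)`, vigorous `[130, Inf)` steps/min.
#'
#' @param records tibble with columns `hr` (> 0) and `sr` (>= first intensity
#'   cut), typically from [align_and_filter()].
#' @param clc_threshold,weak_threshold relative deviation bands.
#' @param intensity_cuts increasing cadence thresholds
#'   (light/moderate/vigorous), steps/min.
#' @return the input tibble with columns `ratio`, `deviation`,
#'   `coupling_class`, `intensity_class` appended.
#' @examples
#' classify_coupling(tibble::tibble(hr = c(100, 100), sr = c(100, 130)))
#' @export
classify_coupling <- function(records, clc_threshold = 0.01,
                              weak_threshold = 0.10,
                              intensity_cuts = c(60, 100, 130)) {
  stopifnot(all(c("hr", "sr") %in% names(records)))
  if (any(records$hr <= 0)) abort("heart rate must be positive for every record")
  records |>
    mutate(
      ratio = .data$sr / .data$hr,
      deviation = abs(.data$ratio - 1),
      coupling_class = coupling_class_of(.data$deviation, clc_threshold, weak_threshold),
      intensity_class = intensity_class_of(.data$sr, intensity_cuts)
    )
}

#' Coupling-class occurrence percentages
#'
#' Shares of active minutes in each coupling class, optionally stratified by
#' intensity class. Percentages within a stratum sum to 100.
#'
#' @param instances classified instances from [classify_coupling()].
#' @param by_intensity also stratify by `intensity_class`?
#' @return tibble with `coupling_class`, `n`, `percentage` (and
#'   `intensity_class` when stratified).
#' @export
occurrence <- function(instances, by_intensity = FALSE) {
  if (nrow(instances) == 0) {
    warn("no instances; empty occurrence summary")
    return(tibble(
      coupling_class = factor(character(), levels = COUPLING_LEVELS),
      n = integer(), percentage = numeric()
    ))
  }
  keys <- if (by_intensity) c("intensity_class", "coupling_class") else "coupling_class"
  out <- instances |>
    summarise(n = dplyr::n(), .by = dplyr::all_of(keys))
  if (by_intensity) {
    out <- tidyr::complete(out,
      intensity_class = factor(INTENSITY_LEVELS, levels = INTENSITY_LEVELS),
      coupling_class = factor(COUPLING_LEVELS, levels = COUPLING_LEVELS),
      fill = list(n = 0L)
    ) |>
      mutate(percentage = 100 * .data$n / pmax(sum(.data$n), 1L), .by = "intensity_class")
  } else {
    out <- tidyr::complete(out,
      coupling_class = factor(COUPLING_LEVELS, levels = COUPLING_LEVELS),
      fill = list(n = 0L)
    ) |>
      mutate(percentage = 100 * .data$n / sum(.data$n))
  }
  arrange(out, dplyr::pick(dplyr::all_of(keys)))
}

# Label a bout from its instances' coupling classes: the strongest class that
# covers at least `min_share` of instances; otherwise the modal class, ties
# resolved towards the stronger class.
bout_class_of <- function(classes, min_share = 0.2) {
  share <- tabulate(as.integer(classes), nbins = 3) / length(classes)
  hit <- which(share >= min_share)
  if (length(hit) > 0) {
    COUPLING_LEVELS[min(hit)]
  } else {
    COUPLING_LEVELS[which.max(share)]
  }
}

#' Segment classified minutes into activity bouts
#'
#' An activity bout is a maximal run of active minutes in which consecutive
#' observations are less than `gap` minutes apart (default 60); a separation
#' of `gap` or more starts a new bout. Duration is the inclusive minute span
#' `end - start + 1`. Each bout is labelled with a coupling class: the
#' strongest class that covers at least 20% of its minutes, else the modal
#' class (ties towards the stronger class).
#'
#' @param instances classified instances, chronologically sorted (one
#'   subject).
#' @param gap minutes; separations `>= gap` split bouts.
#' @param min_share minimum within-bout share for the strongest-class rule.
#' @return tibble of bouts: `bout_id`, `start`, `end`, `duration`,
#'   `n_instances`, `bout_class`, `start_hour`, `clc_share`, `weak_share`.
#' @export
segment_bouts <- function(instances, gap = 60, min_share = 0.2) {
  stopifnot(all(c("timestamp", "coupling_class") %in% names(instances)))
  if (nrow(instances) == 0) {
    return(tibble(
      bout_id = integer(), start = as.POSIXct(character(), tz = "UTC"),
      end = as.POSIXct(character(), tz = "UTC"), duration = numeric(),
      n_instances = integer(),
      bout_class = factor(character(), levels = COUPLING_LEVELS),
      start_hour = integer(), clc_share = numeric(), weak_share = numeric()
    ))
  }
  instances <- arrange(instances, .data$timestamp)
  dt <- as.numeric(difftime(
    instances$timestamp[-1], instances$timestamp[-nrow(instances)],
    units = "mins"
  ))
  instances$bout_id <- cumsum(c(1L, as.integer(dt >= gap)))
  instances |>
    summarise(
      start = min(.data$timestamp),
      end = max(.data$timestamp),
      n_instances = dplyr::n(),
      bout_class = factor(bout_class_of(.data$coupling_class, min_share),
        levels = COUPLING_LEVELS
      ),
      clc_share = mean(.data$coupling_class == "CLC"),
      weak_share = mean(.data$coupling_class == "weak_CLC"),
      .by = "bout_id"
    ) |>
    mutate(
      duration = as.numeric(difftime(.data$end, .data$start, units = "mins")) + 1,
      start_hour = lubridate::hour(.data$start)
    ) |>
    select(
      "bout_id", "start", "end", "duration", "n_instances",
      "bout_class", "start_hour", "clc_share", "weak_share"
    )
}

#' Median activity duration by bout coupling class
#'
#' @param bouts tibble from [segment_bouts()].
#' @return tibble with one row per coupling class present among the bouts:
#'   `bout_class`, `n_bouts`, `median_duration`, `iqr_duration` (minutes).
#' @export
bout_duration_by_class <- function(bouts) {
  if (nrow(bouts) == 0) abort("at least one bout is required")
  bouts |>
    summarise(
      n_bouts = dplyr::n(),
      median_duration = median(.data$duration),
      iqr_duration = iqr_of(.data$duration),
      .by = "bout_class"
    ) |>
    arrange(.data$bout_class)
}

#' Group a subject by moderate-vs-vigorous coupling preference
#'
#' The grouping statistic is `D = occ_moderate - occ_vigorous` in percentage
#' points of CLC occurrence. Groups: `most_vigorous` (`D <= -cutoff`),
#' `most_moderate` (`D >= cutoff`), `constant` otherwise; default cutoff 1.5.
#'
#' @param occ_moderate,occ_vigorous CLC occurrence (%) within the moderate
#'   and vigorous intensity strata, each in `[0, 100]`.
#' @param cutoff percentage points.
#' @return one-row tibble with `d_statistic` and `group`.
#' @examples
#' group_subject(6.84, 4.75)
#' @export
group_subject <- function(occ_moderate, occ_vigorous, cutoff = 1.5) {
  if (is.na(occ_moderate) || is.na(occ_vigorous)) {
    return(tibble(
      d_statistic = NA_real_,
      group = factor(NA_character_, levels = GROUP_LEVELS)
    ))
  }
  stopifnot(
    occ_moderate >= 0, occ_moderate <= 100,
    occ_vigorous >= 0, occ_vigorous <= 100
  )
  d <- occ_moderate - occ_vigorous
  grp <- if (d <= -cutoff) {
    "most_vigorous"
  } else if (d >= cutoff) {
    "most_moderate"
  } else {
    "constant"
  }
  tibble(d_statistic = d, group = factor(grp, levels = GROUP_LEVELS))
}

#' Start-hour distribution of bouts per coupling class
#'
#' Hour-of-day histogram of bout starts for each coupling class, with a
#' Kruskal-Wallis test of start hour across classes (a nonparametric check
#' for an association between time of day and coupling strength).
#'
#' @param bouts tibble from [segment_bouts()].
#' @return list of class `clc_tod_profile` with elements `profile` (tibble:
#'   `bout_class`, `start_hour`, `n`, `proportion`) and `test` (a
#'   [kruskal_wallis_groups()] result, or `NULL` with fewer than two classes).
#' @export
time_of_day_profile <- function(bouts) {
  if (nrow(bouts) == 0) abort("at least one bout is required")
  profile <- bouts |>
    summarise(n = dplyr::n(), .by = c("bout_class", "start_hour")) |>
    mutate(proportion = .data$n / sum(.data$n), .by = "bout_class") |>
    arrange(.data$bout_class, .data$start_hour)
  classes <- droplevels(bouts$bout_class)
  test <- if (nlevels(classes) >= 2) {
    kruskal_wallis_groups(bouts$start_hour, classes)
  } else {
    NULL
  }
  structure(list(profile = profile, test = test), class = "clc_tod_profile")
}

#' @export
print.clc_tod_profile <- function(x, ...) {
  cat("<clc_tod_profile>\n")
  print(x$profile, ...)
  if (!is.null(x$test)) {
    cat(sprintf(
      "Kruskal-Wallis start-hour ~ bout class: H = %.3f, p = %.4g\n",
      x$test$statistic, x$test$p_value
    ))
  }
  invisible(x)
}
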