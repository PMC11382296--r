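# Reading raw wearable streams and building the aligned minute table.

parse_fitbit_time <- function(x) {
  as.POSIXct(x, format = "%m/%d/%y %H:%M:%S", tz = "UTC")
}

log_rejected <- function(file, n, why) {
  if (n > 0) {
    inform(sprintf("%s: rejected %d row(s) (%s)", basename(file), n, why))
  }
}

#' Read a raw heart-rate file
#'
#' Supported dialects: `"csv"` (header `timestamp,bpm`, ISO-8601 timestamps)
#' and `"fitbit-json"` (array of `{"dateTime": "MM/DD/YY HH:MM:SS",
#' "value": {"bpm": ..., "confidence": ...}}`). Rows with unparseable
#' timestamps or with bpm outside the physiological range (20, 250) are
#' counted and reported, never silently dropped; the count is attached as
#' attribute `n_rejected`. Samples are returned in chronological order.
#'
#' @param file path to the raw file.
#' @param dialect `"csv"` or `"fitbit-json"`.
#' @return tibble with columns `timestamp` (POSIXct, UTC wall clock) and
#'   `bpm`, sorted by time, with attribute `n_rejected`.
#' @export
read_heart_rate <- function(file, dialect = c("csv", "fitbit-json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(file)) abort(sprintf("file not found: %s", file))
  if (dialect == "csv") {
    raw <- readr::read_csv(file,
      col_types = readr::cols(
        timestamp = readr::col_datetime(), bpm = readr::col_double()
      ),
      progress = FALSE
    )
    if (!all(c("timestamp", "bpm") %in% names(raw))) {
      abort(sprintf("%s: expected columns `timestamp,bpm`", file))
    }
    n_malformed <- nrow(readr::problems(raw))
  } else {
    parsed <- tryCatch(
      jsonlite::fromJSON(file, simplifyVector = TRUE),
      error = function(e) abort(sprintf("%s: unparseable JSON (%s)", file, conditionMessage(e)))
    )
    if (length(parsed) == 0) {
      raw <- tibble(timestamp = as.POSIXct(character(), tz = "UTC"), bpm = numeric())
      n_malformed <- 0L
    } else {
      if (is.null(parsed$dateTime) || is.null(parsed$value$bpm)) {
        abort(sprintf("%s: not a fitbit-json heart-rate file", file))
      }
      raw <- tibble(
        timestamp = parse_fitbit_time(parsed$dateTime),
        bpm = as.numeric(parsed$value$bpm)
      )
      n_malformed <- 0L
    }
  }
  ok <- !is.na(raw$timestamp) & !is.na(raw$bpm) & raw$bpm > 20 & raw$bpm < 250
  out <- raw[ok, c("timestamp", "bpm")]
  out <- out[order(out$timestamp), ]
  dup <- duplicated(out$timestamp)
  out <- out[!dup, ]
  n_rejected <- n_malformed + sum(!ok) + sum(dup)
  log_rejected(file, n_rejected, "malformed, out-of-range bpm, or duplicate timestamp")
  if (nrow(out) == 0) warn(sprintf("%s: no valid heart-rate samples", file))
  out <- as_tibble(out)
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Read a raw per-minute step file
#'
#' Dialects as in [read_heart_rate()]; the fitbit-json `value` is the step
#' count as an integer or an integer-valued string. Step counts must be
#' integers in `[0, 300]`; non-integer values are rejected (never rounded).
#' Duplicate minutes keep the first record and are reported.
#'
#' @inheritParams read_heart_rate
#' @return tibble with columns `timestamp` (minute resolution) and `steps`
#'   (integer), sorted, with attribute `n_rejected`.
#' @export
read_steps <- function(file, dialect = c("csv", "fitbit-json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(file)) abort(sprintf("file not found: %s", file))
  if (dialect == "csv") {
    raw <- readr::read_csv(file,
      col_types = readr::cols(
        timestamp = readr::col_datetime(), steps = readr::col_double()
      ),
      progress = FALSE
    )
    if (!all(c("timestamp", "steps") %in% names(raw))) {
      abort(sprintf("%s: expected columns `timestamp,steps`", file))
    }
    n_malformed <- nrow(readr::problems(raw))
    steps <- raw$steps
  } else {
    parsed <- tryCatch(
      jsonlite::fromJSON(file, simplifyVector = TRUE),
      error = function(e) abort(sprintf("%s: unparseable JSON (%s)", file, conditionMessage(e)))
    )
    if (length(parsed) == 0) {
      raw <- tibble(timestamp = as.POSIXct(character(), tz = "UTC"))
      steps <- numeric()
      n_malformed <- 0L
    } else {
      if (is.null(parsed$dateTime) || is.null(parsed$value)) {
        abort(sprintf("%s: not a fitbit-json step file", file))
      }
      raw <- tibble(timestamp = parse_fitbit_time(parsed$dateTime))
      steps <- suppressWarnings(as.numeric(parsed$value))
      n_malformed <- 0L
    }
  }
  integral <- !is.na(steps) & steps == floor(steps)
  ok <- !is.na(raw$timestamp) & integral & steps >= 0 & steps <= 300
  out <- tibble(
    timestamp = floor_minute(raw$timestamp[ok]),
    steps = as.integer(steps[ok])
  )
  out <- out[order(out$timestamp), ]
  dup <- duplicated(out$timestamp)
  if (any(dup)) {
    warn(sprintf(
      "%s: %d duplicate minute(s), keeping the first record of each",
      basename(file), sum(dup)
    ))
  }
  out <- out[!dup, ]
  n_rejected <- n_malformed + sum(!ok)
  log_rejected(file, n_rejected, "malformed, non-integer, or out-of-range steps")
  if (nrow(out) == 0) warn(sprintf("%s: no valid step records", file))
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Average heart-rate samples per calendar minute
#'
#' Samples are assigned to the minute their timestamp floor-truncates to; a
#' minute is emitted only if it holds at least `min_samples` samples (default
#' 6, half of the nominal 12 five-second samples), guarding the minute mean
#' against sparse coverage.
#'
#' @param samples tibble from [read_heart_rate()] (columns `timestamp`,
#'   `bpm`), chronologically sorted.
#' @param min_samples minimum samples per minute for the minute to be kept.
#' @return tibble with `timestamp` (minute), `hr` (mean bpm), `n_samples`.
#' @export
minutely_hr <- function(samples, min_samples = 6) {
  stopifnot(all(c("timestamp", "bpm") %in% names(samples)))
  if (nrow(samples) == 0) {
    return(tibble(
      timestamp = as.POSIXct(character(), tz = "UTC"),
      hr = numeric(), n_samples = integer()
    ))
  }
  minute <- as.numeric(samples$timestamp) %/% 60
  sums <- rowsum(cbind(samples$bpm, 1), minute)
  out <- tibble(
    timestamp = as.POSIXct(as.numeric(rownames(sums)) * 60,
      tz = "UTC", origin = "1970-01-01"
    ),
    hr = unname(sums[, 1] / sums[, 2]),
    n_samples = as.integer(sums[, 2])
  )
  out |>
    filter(.data$n_samples >= min_samples) |>
    arrange(.data$timestamp)
}

#' Synchronise heart rate and step rate and apply the activity filter
#'
#' Inner-joins the per-minute heart-rate and step tables on the minute
#' timestamp, then keeps only minutes with `sr >= sr_threshold` (strictly
#' below-threshold minutes are excluded; 60 steps/min is the conventional
#' slow-walking cut separating locomotion from rest).
#'
#' @param hr_minutes tibble from [minutely_hr()].
#' @param sr_minutes tibble from [read_steps()].
#' @param sr_threshold steps/min activity threshold (default 60).
#' @return tibble of aligned active minutes: `timestamp`, `hr`, `sr`.
#' @export
align_and_filter <- function(hr_minutes, sr_minutes, sr_threshold = 60) {
  stopifnot(
    all(c("timestamp", "hr") %in% names(hr_minutes)),
    all(c("timestamp", "steps") %in% names(sr_minutes))
  )
  out <- inner_join(
    hr_minutes[, c("timestamp", "hr")],
    tibble(
      timestamp = floor_minute(sr_minutes$timestamp),
      sr = as.numeric(sr_minutes$steps)
    ),
    by = "timestamp"
  ) |>
    filter(.data$sr >= sr_threshold) |>
    arrange(.data$timestamp)
  if (nrow(out) == 0) warn("no active minutes after alignment and filtering")
  out
}
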