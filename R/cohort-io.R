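# Writing synthetic cohorts to disk in the supported raw-file dialects.

fitbit_time <- function(x) format(x, "%m/%d/%y %H:%M:%S", tz = "UTC")

write_subject_files <- function(streams, dir, dialects) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if ("csv" %in% dialects) {
    readr::write_csv(streams$heart_rate, file.path(dir, "heart_rate.csv"))
    readr::write_csv(streams$steps, file.path(dir, "steps.csv"))
  }
  if ("fitbit-json" %in% dialects) {
    hr <- data.frame(
      dateTime = fitbit_time(streams$heart_rate$timestamp),
      value = I(data.frame(
        bpm = streams$heart_rate$bpm,
        confidence = rep(2L, nrow(streams$heart_rate))
      ))
    )
    jsonlite::write_json(hr, file.path(dir, "heart_rate.json"),
      auto_unbox = FALSE, digits = NA
    )
    st <- data.frame(
      dateTime = fitbit_time(streams$steps$timestamp),
      value = as.character(streams$steps$steps)
    )
    jsonlite::write_json(st, file.path(dir, "steps.json"),
      auto_unbox = FALSE, digits = NA
    )
  }
  truth <- streams$truth$minutes
  readr::write_csv(
    tibble(
      timestamp = truth$timestamp,
      entrained_flag = as.integer(truth$entrained),
      scheduled_cadence = truth$scheduled_cadence,
      bout_id = truth$bout_id,
      true_sr = truth$true_sr,
      true_hr = truth$true_hr,
      emitted_sr = truth$emitted_sr
    ),
    file.path(dir, "ground_truth.csv")
  )
  readr::write_csv(streams$truth$bouts, file.path(dir, "ground_truth_bouts.csv"))
  invisible(dir)
}

#' Generate a synthetic cohort on disk
#'
#' Runs [generate_subject()] for every subject in the configuration and
#' writes one subdirectory per subject containing the heart-rate and step
#' streams in the requested raw dialects, a per-minute ground-truth sidecar
#' (`ground_truth.csv`: timestamp, entrained flag, scheduled cadence, ...) and
#' a per-bout sidecar, plus a cohort `manifest.json` recording the
#' configuration and per-subject seeds and record counts. Output is
#' byte-identical across runs with the same configuration.
#'
#' @param config a [cohort_config()].
#' @param output_dir directory to populate (created if missing).
#' @param dialects raw-file dialects to write; any of `"csv"`,
#'   `"fitbit-json"`.
#' @param force overwrite an existing manifest if `TRUE`.
#' @return the manifest, invisibly (a list; also written as JSON).
#' @export
generate_cohort <- function(config, output_dir,
                            dialects = c("csv", "fitbit-json"),
                            force = FALSE) {
  validate_cohort_config(config)
  dialects <- match.arg(dialects, c("csv", "fitbit-json"), several.ok = TRUE)
  manifest_path <- file.path(output_dir, "manifest.json")
  if (file.exists(manifest_path) && !force) {
    abort(sprintf(
      "cohort manifest already exists at %s; use `force = TRUE` to overwrite",
      manifest_path
    ))
  }
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)

  subjects <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    streams <- generate_subject(config, i)
    sdir <- file.path(output_dir, streams$subject_id)
    write_subject_files(streams, sdir, dialects)
    subjects[[i]] <- list(
      subject_id = streams$subject_id,
      dir = streams$subject_id,
      seed = streams$seed,
      n_hr_samples = nrow(streams$heart_rate),
      n_step_minutes = nrow(streams$steps),
      n_bouts = nrow(streams$truth$bouts),
      n_bout_minutes = sum(streams$truth$minutes$in_bout),
      n_entrained_minutes = sum(streams$truth$minutes$entrained)
    )
  }
  manifest <- list(
    package = "clcoupling",
    dialects = as.list(dialects),
    config = unclass(config),
    subjects = subjects
  )
  jsonlite::write_json(manifest, manifest_path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  inform(sprintf(
    "wrote synthetic cohort: %d subjects x %d days in %s",
    config$n_subjects, config$days, output_dir
  ))
  invisible(manifest)
}

#' Read a cohort manifest written by [generate_cohort()]
#'
#' @param path the cohort directory or the manifest file itself.
#' @return the manifest as a list.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  if (!file.exists(path)) abort(sprintf("no manifest found at %s", path))
  jsonlite::read_json(path, simplifyVector = FALSE)
}
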