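# Cohort-level aggregation: medians (IQR) across subjects, headline paired
# contrasts, grouping table, optional age split.

#' Run the full pipeline for a cohort
#'
#' Accepts either a cohort directory written by [generate_cohort()] (its
#' `manifest.json` is used to locate the per-subject files) or a list of
#' per-subject inputs, each a list with elements `heart_rate` and `steps`
#' (paths or tibbles) and optionally `subject_id`. Subjects with no
#' post-filter minutes are excluded from cohort aggregation with a warning.
#'
#' Cohort numbers follow the median (inter-quartile range) convention:
#' every numeric field of the per-subject summaries is aggregated as the
#' across-subject median and IQR. Headline paired contrasts (Wilcoxon
#' signed-rank with r = |Z|/sqrt(N)): CLC occurrence moderate vs light,
#' observed vs null probability of the combined CLC + weak band, and bout
#' duration CLC vs no-CLC. With demographics (`age`), median R is compared
#' across age groups (boundary `config$age_split`) by Kruskal-Wallis with
#' eta-squared.
#'
#' @param cohort a directory containing `manifest.json`, or a list of
#'   subject input lists.
#' @param config an [analysis_config()].
#' @param demographics optional data frame with `subject_id` and any of
#'   `age`, `height`, `gender`; never imputed.
#' @return object of class `clc_cohort_report` with `$subjects` (one row per
#'   subject), `$summary` (long tibble: metric, median, iqr), `$tests`
#'   (tidy test results), `$groups` (per-group characteristics),
#'   `$reports` (the per-subject report objects).
#' @export
run_cohort <- function(cohort, config = analysis_config(),
                       demographics = NULL) {
  inputs <- cohort_inputs(cohort, config)
  if (length(inputs) < 2) abort("a cohort needs at least 2 subjects")
  reports <- lapply(inputs, function(inp) {
    run_subject(inp$heart_rate, inp$steps,
      config = config,
      subject_id = inp$subject_id
    )
  })
  names(reports) <- vapply(reports, function(r) r$subject_id, character(1))
  empty <- vapply(reports, function(r) r$empty, logical(1))
  if (all(empty)) abort("all subjects are empty after filtering")
  if (any(empty)) {
    warn(sprintf(
      "excluding %d empty subject(s) from cohort aggregation: %s",
      sum(empty), paste(names(reports)[empty], collapse = ", ")
    ))
  }
  kept <- reports[!empty]
  subjects <- purrr::list_rbind(lapply(kept, tidy))
  if (!is.null(demographics)) {
    subjects <- left_join(subjects, as_tibble(demographics), by = "subject_id")
  }

  numeric_cols <- names(subjects)[vapply(subjects, is.numeric, logical(1))]
  summary <- subjects |>
    tidyr::pivot_longer(dplyr::all_of(numeric_cols),
      names_to = "metric", values_to = "value"
    ) |>
    summarise(
      median = median(.data$value, na.rm = TRUE),
      iqr = iqr_of(.data$value[!is.na(.data$value)]),
      n_subjects = sum(!is.na(.data$value)),
      .by = "metric"
    )

  tests <- cohort_tests(subjects, config)

  groups <- subjects |>
    filter(!is.na(.data$group)) |>
    summarise(
      n_subjects = dplyr::n(),
      clc_pct_median = median(.data$clc_pct),
      r_median = median(.data$r_median),
      vigorous_share_median = median(.data$vigorous_share_pct),
      resting_hr_median = median(.data$resting_hr_median),
      n_instances_median = median(.data$n_instances),
      .by = "group"
    ) |>
    arrange(.data$group)

  structure(
    list(
      subjects = subjects, summary = summary, tests = tests,
      groups = groups, reports = reports, config = config
    ),
    class = "clc_cohort_report"
  )
}

cohort_inputs <- function(cohort, config) {
  if (is.character(cohort) && length(cohort) == 1) {
    manifest <- read_manifest(cohort)
    base <- if (dir.exists(cohort)) cohort else dirname(cohort)
    ext <- if (config$dialect == "csv") "csv" else "json"
    return(lapply(manifest$subjects, function(s) {
      list(
        subject_id = s$subject_id,
        heart_rate = file.path(base, s$dir, paste0("heart_rate.", ext)),
        steps = file.path(base, s$dir, paste0("steps.", ext))
      )
    }))
  }
  stopifnot(is.list(cohort))
  lapply(seq_along(cohort), function(i) {
    inp <- cohort[[i]]
    stopifnot(!is.null(inp$heart_rate), !is.null(inp$steps))
    inp$subject_id <- inp$subject_id %||% sprintf("S%02d", i)
    inp
  })
}

cohort_tests <- function(subjects, config) {
  out <- list()
  n <- nrow(subjects)
  if (n >= 5) {
    out$clc_moderate_vs_light <- wilcoxon_paired(
      subjects$clc_moderate_pct, subjects$clc_light_pct
    )
    out$observed_vs_null_p_weak_or_clc <- wilcoxon_paired(
      subjects$observed_p_weak_or_clc, subjects$null_p_weak_or_clc
    )
    out$observed_vs_null_iqr <- wilcoxon_paired(
      subjects$observed_iqr, subjects$null_iqr
    )
    out$observed_vs_null_skewness <- wilcoxon_paired(
      subjects$observed_skewness, subjects$null_skewness
    )
    ok <- !is.na(subjects$duration_median_clc) &
      !is.na(subjects$duration_median_no)
    if (sum(ok) >= 5) {
      out$duration_clc_vs_no <- wilcoxon_paired(
        subjects$duration_median_clc[ok], subjects$duration_median_no[ok]
      )
    }
  }
  if ("age" %in% names(subjects) && sum(!is.na(subjects$age)) >= 5) {
    age_group <- factor(
      ifelse(subjects$age >= config$age_split, "older", "younger")
    )
    if (nlevels(droplevels(age_group[!is.na(subjects$age)])) == 2) {
      keep <- !is.na(subjects$age)
      out$r_median_by_age_group <- kruskal_wallis_groups(
        subjects$r_median[keep], age_group[keep]
      )
    }
  }
  purrr::list_rbind(
    lapply(names(out), function(nm) mutate(tidy(out[[nm]]), contrast = nm, .before = 1))
  )
}

#' @export
print.clc_cohort_report <- function(x, ...) {
  pick <- function(m) x$summary[x$summary$metric == m, ]
  cat(sprintf(
    "<clc_cohort_report> %d subjects (%d analysed)\n",
    length(x$reports), nrow(x$subjects)
  ))
  for (m in c("clc_pct", "weak_clc_pct", "r_median", "observed_p_weak_or_clc", "null_p_weak_or_clc")) {
    row <- pick(m)
    if (nrow(row)) {
      cat(sprintf("  %-24s median %.3f (IQR %.3f)\n", m, row$median, row$iqr))
    }
  }
  invisible(x)
}

#' @method tidy clc_cohort_report
#' @export
tidy.clc_cohort_report <- function(x, ...) x$summary

#' @method glance clc_cohort_report
#' @export
glance.clc_cohort_report <- function(x, ...) {
  pick <- function(m) x$summary$median[x$summary$metric == m]
  tibble(
    n_subjects = nrow(x$subjects),
    clc_pct = pick("clc_pct"),
    weak_clc_pct = pick("weak_clc_pct"),
    r_median = pick("r_median"),
    observed_p_weak_or_clc = pick("observed_p_weak_or_clc"),
    null_p_weak_or_clc = pick("null_p_weak_or_clc"),
    delta_p = pick("delta_p")
  )
}
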