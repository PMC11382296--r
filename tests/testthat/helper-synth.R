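# Shared fixture builders; everything is generated in code at test time.

minute_ts <- function(mins, origin = "2020-01-01 08:00:00") {
  as.POSIXct(origin, tz = "UTC") + 60 * mins
}

# a minimal aligned-minute table
make_records <- function(sr, hr, mins = seq_along(sr) - 1) {
  tibble::tibble(timestamp = minute_ts(mins), hr = hr, sr = sr)
}

# small cohort config used across tests; noise switched off where noted
test_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 2, days = 7, seed = 42),
    list(...)
  )
  do.call(cohort_config, args)
}

noiseless <- function(...) {
  test_config(hr_noise_mape = 0, sr_bias = 0, sr_jitter_sd = 0, ...)
}

# run ingest + classification for one generated subject
subject_instances <- function(streams, config = analysis_config()) {
  m <- minutely_hr(streams$heart_rate, config$min_hr_samples)
  a <- suppressWarnings(align_and_filter(m, streams$steps, config$sr_threshold))
  classify_coupling(a, config$clc_threshold, config$weak_threshold,
    config$intensity_cuts)
}

# brute-force random-pairing oracle: enumerate all N^2 ratios
brute_null <- function(hr, sr, edges = clc_bins()) {
  r <- as.vector(outer(sr, 1 / hr))
  list(
    histogram = c(
      sum(r < edges[1]),
      diff(vapply(edges, function(e) sum(r < e), numeric(1))),
      sum(r >= edges[length(edges)])
    ) / length(r),
    p_clc = mean(abs(r - 1) <= 0.01),
    p_weak_or_clc = mean(abs(r - 1) <= 0.10),
    median = unname(quantile(r, 0.5, type = 1)),
    iqr = unname(diff(quantile(r, c(0.25, 0.75), type = 1))),
    skewness = {
      m <- mean(r)
      mean((r - m)^3) / mean((r - m)^2)^1.5
    }
  )
}
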