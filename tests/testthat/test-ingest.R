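write_hr_csv <- function(lines, path = withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())) {
  writeLines(c("timestamp,bpm", lines), path)
  path
}

write_steps_csv <- function(lines, path = withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())) {
  writeLines(c("timestamp,steps", lines), path)
  path
}

test_that("heart-rate reader parses both dialects, sorts, and counts rejects", {
  f <- write_hr_csv(c(
    "2020-01-01T08:00:10Z,80",
    "2020-01-01T08:00:00Z,70",
    "2020-01-01T08:00:05Z,75"
  ))
  hr <- read_heart_rate(f)
  expect_equal(nrow(hr), 3)
  expect_true(!is.unsorted(hr$timestamp))
  expect_equal(hr$bpm, c(70, 75, 80))
  expect_equal(attr(hr, "n_rejected"), 0L)

  # bpm = 0 violates the physiological range and is counted, not dropped
  # silently
  f2 <- write_hr_csv(c("2020-01-01T08:00:00Z,0", "2020-01-01T08:00:05Z,72"))
  hr2 <- suppressMessages(read_heart_rate(f2))
  expect_equal(nrow(hr2), 1)
  expect_equal(attr(hr2, "n_rejected"), 1L)

  jf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    data.frame(
      dateTime = c("01/01/20 08:00:00", "01/01/20 08:00:05"),
      value = I(data.frame(bpm = c(64L, 66L), confidence = c(2L, 3L)))
    ),
    jf, auto_unbox = FALSE
  )
  hrj <- read_heart_rate(jf, dialect = "fitbit-json")
  expect_equal(hrj$bpm, c(64, 66))
  expect_s3_class(hrj$timestamp, "POSIXct")

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(read_heart_rate(bad, dialect = "fitbit-json"), "unparseable")
})

test_that("step reader enforces integer steps and keeps first duplicate minute", {
  f <- write_steps_csv(c(
    "2020-01-01T08:00:00Z,95",
    "2020-01-01T08:01:00Z,100",
    "2020-01-01T08:02:00Z,105"
  ))
  st <- read_steps(f)
  expect_equal(nrow(st), 3)

  f2 <- write_steps_csv(c(
    "2020-01-01T08:00:00Z,95",
    "2020-01-01T08:00:00Z,90"
  ))
  expect_warning(st2 <- read_steps(f2), "duplicate")
  expect_equal(st2$steps, 95L)

  # non-integer and out-of-range values are rejected, never rounded
  f3 <- write_steps_csv(c(
    "2020-01-01T08:00:00Z,95.5",
    "2020-01-01T08:01:00Z,350",
    "2020-01-01T08:02:00Z,-3",
    "2020-01-01T08:03:00Z,100"
  ))
  st3 <- suppressMessages(read_steps(f3))
  expect_equal(st3$steps, 100L)
  expect_equal(attr(st3, "n_rejected"), 3L)
})

test_that("empty files give empty sequences with a warning", {
  f <- write_hr_csv(character())
  expect_warning(hr <- read_heart_rate(f), "no valid")
  expect_equal(nrow(hr), 0)
})

test_that("minute averaging floors timestamps and enforces the completeness rule", {
  base <- as.POSIXct("2020-01-01 08:00:00", tz = "UTC")
  samples <- tibble::tibble(
    timestamp = base + c(seq(0, 55, by = 5), 60, 65),
    bpm = c(rep(60, 12), 58, 62)
  )
  m <- minutely_hr(samples, min_samples = 3)
  # the second minute has only 2 samples and is omitted
  expect_equal(nrow(m), 1)
  expect_equal(m$hr, 60)
  m2 <- minutely_hr(samples, min_samples = 2)
  expect_equal(m2$hr, c(60, 60))
  expect_equal(m2$timestamp, base + c(0, 60))

  sym <- tibble::tibble(timestamp = base + c(0, 5, 10), bpm = c(58, 60, 62))
  expect_equal(minutely_hr(sym, min_samples = 3)$hr, 60)
})

test_that("alignment inner-joins on the minute and applies the >= 60 filter", {
  base <- as.POSIXct("2020-01-01 08:00:00", tz = "UTC")
  hrm <- tibble::tibble(timestamp = base + 60 * (0:3), hr = c(100, 100, 100, 100))
  srm <- tibble::tibble(timestamp = base + 60 * (0:2), steps = c(59L, 60L, 100L))
  a <- align_and_filter(hrm, srm)
  # sr = 59 excluded (strictly below), sr = 60 retained, unmatched hr minute
  # dropped by the join
  expect_equal(a$sr, c(60, 100))
  expect_equal(nrow(a), 2)

  expect_warning(
    align_and_filter(hrm, tibble::tibble(timestamp = base + 36000, steps = 100L)),
    "no active minutes"
  )
})

test_that("join is symmetric and the filter is monotone in the threshold", {
  s <- generate_subject(test_config(days = 2), 1)
  m <- minutely_hr(s$heart_rate)
  a1 <- align_and_filter(m, s$steps)
  # swapping which table is first in the join logic cannot change the set:
  # emulate by joining steps-first manually
  keys <- intersect(m$timestamp, s$steps$timestamp[s$steps$steps >= 60])
  expect_setequal(as.numeric(a1$timestamp), keys)
  n_by_thr <- vapply(
    c(60, 80, 100, 130),
    function(thr) nrow(align_and_filter(m, s$steps, thr)),
    numeric(1)
  )
  expect_true(all(diff(n_by_thr) <= 0))
})

test_that("generator output round-trips through both dialects losslessly", {
  dir <- withr::local_tempdir()
  cfg <- noiseless(days = 2)
  suppressMessages(generate_cohort(cfg, dir))
  s <- generate_subject(cfg, 1)
  hr_csv <- read_heart_rate(file.path(dir, "S01", "heart_rate.csv"))
  hr_json <- read_heart_rate(file.path(dir, "S01", "heart_rate.json"), "fitbit-json")
  expect_equal(nrow(hr_csv), nrow(s$heart_rate))
  expect_equal(hr_csv$bpm, s$heart_rate$bpm)
  expect_equal(hr_csv$timestamp, s$heart_rate$timestamp)
  expect_equal(hr_json$bpm, hr_csv$bpm)
  expect_equal(hr_json$timestamp, hr_csv$timestamp)
  st_csv <- read_steps(file.path(dir, "S01", "steps.csv"))
  st_json <- read_steps(file.path(dir, "S01", "steps.json"), "fitbit-json")
  expect_equal(st_csv$steps, s$steps$steps)
  expect_equal(st_json$steps, s$steps$steps)

  # aligned minute table equals the generator's own noiseless truth
  m <- minutely_hr(hr_csv)
  a <- align_and_filter(m, st_csv)
  truth <- s$truth$minutes
  active <- truth[truth$emitted_sr >= 60, ]
  expect_equal(nrow(a), nrow(active))
  expect_equal(a$sr, as.numeric(active$emitted_sr))
  # minute HR is the mean of 12 identical rounded samples
  expect_equal(a$hr, round(active$true_hr)[match(a$timestamp, active$timestamp)])
})
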