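test_that("coupling and intensity classification hit the band boundaries exactly", {
  rec <- make_records(
    sr = c(100, 99, 90, 88, 130, 60),
    hr = c(100, 100, 100, 100, 100, 100)
  )
  ci <- classify_coupling(rec)
  expect_equal(ci$ratio, rec$sr / rec$hr)
  expect_equal(ci$deviation, abs(rec$sr / rec$hr - 1))
  expect_equal(
    as.character(ci$coupling_class),
    c("CLC", "CLC", "weak_CLC", "no_CLC", "no_CLC", "no_CLC")
  )
  expect_equal(
    as.character(ci$intensity_class),
    c("moderate", "light", "light", "light", "vigorous", "light")
  )
  # classification is total: one coupling and one intensity class each
  expect_false(any(is.na(ci$coupling_class)))
  expect_false(any(is.na(ci$intensity_class)))
  expect_error(classify_coupling(make_records(100, 0)), "positive")
})

test_that("tightening the CLC band never increases CLC occurrence", {
  set.seed(1)
  rec <- make_records(sr = runif(500, 60, 180), hr = runif(500, 60, 180))
  occs <- vapply(c(0.005, 0.01, 0.02, 0.05), function(thr) {
    ci <- classify_coupling(rec, clc_threshold = thr)
    mean(ci$coupling_class == "CLC")
  }, numeric(1))
  expect_true(all(diff(occs) >= 0))
})

test_that("occurrence percentages count classes and sum to 100 per stratum", {
  rec <- make_records(sr = c(100, 150), hr = c(100, 100))
  occ <- occurrence(classify_coupling(rec))
  expect_equal(occ$percentage, c(50, 0, 50))
  expect_equal(sum(occ$percentage), 100)

  all_clc <- occurrence(classify_coupling(make_records(c(100, 120), c(100, 120))))
  expect_equal(all_clc$percentage, c(100, 0, 0))

  strat <- occurrence(
    classify_coupling(make_records(c(100, 150, 135), c(100, 100, 135))),
    by_intensity = TRUE
  )
  sums <- tapply(strat$percentage, strat$intensity_class, sum)
  expect_equal(as.numeric(sums[c("moderate", "vigorous")]), c(100, 100))
  expect_warning(occurrence(classify_coupling(make_records(numeric(), numeric()))))
})

test_that("bout segmentation splits at gaps of 60 minutes or more", {
  one <- classify_coupling(make_records(
    sr = rep(100, 12), hr = rep(100, 12), mins = c(0:10, 69)
  ))
  expect_equal(nrow(segment_bouts(one)), 1)

  two <- classify_coupling(make_records(
    sr = rep(100, 12), hr = rep(100, 12), mins = c(0:10, 70)
  ))
  b <- segment_bouts(two)
  expect_equal(nrow(b), 2)
  expect_equal(b$duration, c(11, 1))
  expect_equal(b$n_instances, c(11L, 1L))

  # idempotent and order-stable
  shuffled <- two[sample(nrow(two)), ]
  expect_equal(segment_bouts(shuffled), b)
})

test_that("bout labels use the strongest-class-over-20% rule", {
  # 3 CLC of 12 instances = 25% -> CLC even though no_CLC is modal
  rec <- make_records(
    sr = c(rep(100, 3), rep(150, 9)),
    hr = rep(100, 12)
  )
  b <- segment_bouts(classify_coupling(rec))
  expect_equal(as.character(b$bout_class), "CLC")
  # 1 CLC of 12 (8%) -> falls back to modal class
  rec2 <- make_records(
    sr = c(100, rep(150, 11)),
    hr = rep(100, 12)
  )
  b2 <- segment_bouts(classify_coupling(rec2))
  expect_equal(as.character(b2$bout_class), "no_CLC")
})

test_that("bout segmentation recovers the generator's schedule", {
  s <- generate_subject(test_config(days = 10), 2)
  ci <- subject_instances(s)
  b <- segment_bouts(ci)
  # scheduled bouts are >= 90 min apart, but bouts whose slow-cadence minutes
  # all fall below the filter can vanish; every recovered bout must map to
  # exactly one scheduled bout
  sched <- s$truth$bouts
  idx <- lapply(seq_len(nrow(b)), function(i) {
    which(sched$start <= b$start[i] & sched$end >= b$end[i])
  })
  expect_true(all(lengths(idx) == 1))
  # with bouts separated by >= 90 min, most scheduled bouts survive the
  # activity filter and come back as exactly one segment
  expect_gte(length(unique(unlist(idx))), nrow(sched) * 0.8)
})

test_that("duration summaries are per-class medians with absent classes absent", {
  b <- tibble::tibble(
    bout_id = 1:4,
    duration = c(10, 20, 30, 40),
    bout_class = factor(c("CLC", "CLC", "CLC", "weak_CLC"),
      levels = c("CLC", "weak_CLC", "no_CLC")
    )
  )
  d <- bout_duration_by_class(b)
  expect_equal(d$median_duration[d$bout_class == "CLC"], 20)
  expect_equal(d$median_duration[d$bout_class == "weak_CLC"], 40)
  expect_false("no_CLC" %in% as.character(d$bout_class))
  expect_error(bout_duration_by_class(b[0, ]), "at least one")
})

test_that("entrainment concentrated in long bouts lengthens CLC-labelled bouts", {
  # duration-weighted entrainment plus wide duration spread: CLC bouts
  # should be longer than no-CLC bouts on median
  cfg <- cohort_config(
    n_subjects = 1, days = 60, seed = 11, couple_fraction = 0.25,
    hr_noise_mape = 0, sr_bias = 0, sr_jitter_sd = 0,
    bout_duration_mean = 50, bout_duration_sd = 45
  )
  s <- generate_subject(cfg, 1)
  b <- segment_bouts(subject_instances(s))
  d <- bout_duration_by_class(b)
  med <- setNames(d$median_duration, as.character(d$bout_class))
  expect_true(all(c("CLC", "no_CLC") %in% names(med)))
  expect_gt(med[["CLC"]], med[["no_CLC"]])
})

test_that("the grouping statistic D assigns groups with closed boundaries", {
  g <- group_subject(6.84, 4.75)
  expect_equal(g$d_statistic, 2.09)
  expect_equal(as.character(g$group), "most_moderate")
  expect_equal(as.character(group_subject(5, 3.5)$group), "most_moderate")
  expect_equal(as.character(group_subject(3.5, 5)$group), "most_vigorous")
  expect_equal(as.character(group_subject(4, 4)$group), "constant")
  expect_equal(as.character(group_subject(5, 4)$group), "constant")
  expect_true(is.na(group_subject(NA, 4)$group))
  expect_error(group_subject(120, 4))
})

test_that("time-of-day profiles histogram bout starts per class", {
  b <- tibble::tibble(
    bout_id = 1:2,
    start_hour = c(9L, 18L),
    bout_class = factor(c("CLC", "CLC"), levels = c("CLC", "weak_CLC", "no_CLC"))
  )
  prof <- time_of_day_profile(b)
  expect_equal(prof$profile$proportion, c(0.5, 0.5))
  expect_null(prof$test)

  b2 <- tibble::tibble(
    bout_id = 1:12,
    start_hour = rep(12L, 12),
    bout_class = factor(rep(c("CLC", "no_CLC"), 6),
      levels = c("CLC", "weak_CLC", "no_CLC")
    )
  )
  prof2 <- time_of_day_profile(b2)
  expect_equal(nrow(prof2$profile), 2)
  expect_equal(prof2$profile$proportion, c(1, 1))
})

test_that("uniform bout starts show no class-hour association at the nominal rate", {
  ps <- vapply(1:20, function(seed) {
    cfg <- cohort_config(
      n_subjects = 1, days = 30, seed = 100 + seed,
      couple_fraction = 0.1
    )
    b <- segment_bouts(subject_instances(generate_subject(cfg, 1)))
    prof <- time_of_day_profile(b)
    if (is.null(prof$test)) NA_real_ else prof$test$p_value
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  expect_gte(mean(ps > 0.05), 0.9)
})
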