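test_that("degenerate single-value inputs give all mass at their ratio", {
  expect_error(null_exact(100, 100), "at least two")
  ne <- null_exact(c(100, 100), c(100, 100))
  expect_equal(ne$p_clc, 1)
  h <- ne$histogram
  expect_equal(sum(h$probability), 1)
  expect_equal(h$probability[h$bin_left <= 1 & h$bin_right > 1], 1)
  expect_equal(ne$median, 1)
})

test_that("a hand-enumerable pairing gives p_clc = 0.5", {
  # pairs: 100/100, 200/100, 100/100, 200/100 -> ratios 1, 2, 1, 2
  ne <- null_exact(c(100, 100), c(100, 200))
  expect_equal(ne$p_clc, 0.5)
  expect_equal(ne$p_weak_or_clc, 0.5)
  expect_equal(sum(ne$histogram$probability), 1)
})

test_that("exact null equals brute-force N^2 enumeration on random inputs", {
  set.seed(2024)
  for (rep in 1:25) {
    n_h <- sample(5:200, 1)
    n_s <- sample(5:200, 1)
    hr <- runif(n_h, 45, 200)
    sr <- runif(n_s, 20, 250)
    ne <- null_exact(hr, sr)
    bf <- brute_null(hr, sr)
    expect_lt(max(abs(ne$histogram$probability - bf$histogram)), 1e-12)
    expect_lt(abs(ne$p_clc - bf$p_clc), 1e-12)
    expect_lt(abs(ne$p_weak_or_clc - bf$p_weak_or_clc), 1e-12)
    expect_equal(ne$median, bf$median, tolerance = 1e-9)
    expect_equal(ne$iqr, bf$iqr, tolerance = 1e-9)
    expect_equal(ne$skewness, bf$skewness, tolerance = 1e-9)
  }
})

test_that("exact null is invariant to permutations of either input", {
  set.seed(5)
  hr <- runif(80, 60, 180)
  sr <- runif(80, 60, 180)
  a <- null_exact(hr, sr)
  b <- null_exact(sample(hr), sample(sr))
  expect_equal(a$histogram, b$histogram)
  expect_equal(a$p_clc, b$p_clc)
  expect_equal(a$median, b$median)
})

test_that("sampled null is seeded, reproducible, and converges to the exact null", {
  set.seed(7)
  hr <- runif(60, 60, 180)
  sr <- runif(60, 60, 180)
  s1 <- null_sampled(hr, sr, n_samples = 2e4, seed = 9)
  s2 <- null_sampled(hr, sr, n_samples = 2e4, seed = 9)
  expect_identical(s1$draws, s2$draws)
  expect_error(null_sampled(hr, sr, n_samples = 100), "10,000")

  ne <- null_exact(hr, sr)
  big <- null_sampled(hr, sr, n_samples = 1e6, seed = 3)
  for (field in c("p_clc", "p_weak_or_clc")) {
    se <- sqrt(ne[[field]] * (1 - ne[[field]]) / 1e6)
    expect_lt(abs(big[[field]] - ne[[field]]), 3 * se)
  }

  one <- null_sampled(100, 100, n_samples = 1e4, seed = 1)
  expect_true(all(one$draws == 1))
})

test_that("observed distribution summarises ratios with peak and band shares", {
  ob <- observed_distribution(rep(1.0, 10))
  expect_equal(ob$peak_bin, c(1.0, 1.01))
  expect_equal(ob$peak_probability, 1)
  expect_equal(ob$p_clc, 1)

  ob3 <- observed_distribution(c(0.95, 1.0, 1.3))
  expect_equal(ob3$p_clc, 1 / 3)
  expect_equal(ob3$p_weak_or_clc, 2 / 3)
})

test_that("comparing a distribution with itself gives zero distance", {
  set.seed(11)
  sr <- runif(200, 60, 180)
  # constant heart rate: the null pairing distribution equals the observed
  # ratio distribution exactly
  ob <- observed_distribution(sr / 100)
  ne <- null_exact(c(100, 100), sr)
  cmp <- compare_distributions(ob, ne)
  # identical value sets can still differ by one count at an atom because
  # (s/h)*h rounds below s in floating point; allow that single step
  expect_lte(cmp$ks_statistic, 1 / 200 + 1e-12)
  expect_equal(cmp$delta_p, 0)
  expect_equal(cmp$ks_p, 1)
})

test_that("grid mismatch is an error", {
  ob <- observed_distribution(c(0.9, 1, 1.1), edges = clc_bins(0.5, 2))
  ne <- null_exact(c(100, 100), c(90, 110))
  expect_error(compare_distributions(ob, ne), "bin grid")
})

test_that("one-sample KS against the exact null matches ks.test on continuous data", {
  set.seed(13)
  hr <- runif(150, 60, 180)
  sr <- runif(150, 60, 180)
  x <- runif(120, 0.5, 2.5)
  ob <- observed_distribution(x)
  ne <- null_exact(hr, sr)
  cmp <- compare_distributions(ob, ne)
  f <- function(q) {
    vapply(q, function(qi) mean(outer(sr, 1 / hr) <= qi), numeric(1))
  }
  ref <- suppressWarnings(stats::ks.test(x, f))
  expect_equal(cmp$ks_statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_lt(abs(cmp$ks_p - ref$p.value), 0.02)
})

test_that("entrainment shifts the observed distribution away from its null", {
  # noiseless full entrainment: every observed ratio is 1 while the null
  # spreads over the pairing distribution
  cfg <- cohort_config(
    n_subjects = 1, days = 7, seed = 21, couple_fraction = 1,
    hr_noise_mape = 0, sr_bias = 0, sr_jitter_sd = 0
  )
  ci <- subject_instances(generate_subject(cfg, 1))
  expect_true(all(ci$coupling_class == "CLC"))
  ob <- observed_distribution(ci)
  ne <- null_exact(ci$hr, ci$sr)
  expect_equal(ob$p_clc, 1)
  expect_lt(ne$p_clc, 1)
  cmp <- compare_distributions(ob, ne)
  expect_lt(cmp$ks_p, 0.001)
  expect_gt(cmp$delta_p, 0)
})
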