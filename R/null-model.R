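# Random-pairing null distribution of the coupling ratio.
#
# The null hypothesis is that a subject's heart-rate and step-rate values are
# paired at random: R_sim = sr[j] / hr[i] over all N x N index pairs. The
# exact method computes bin masses and band probabilities by sorting the
# step-rate values once and counting, per heart-rate value, how many step
# rates fall below each scaled bin edge -- identical to enumerating all N^2
# pairs but O(B * N log N).

#' Histogram bin edges for coupling-ratio distributions
#'
#' 1%-wide bins spanning `[0.3, 3.0)`, the ratio range reachable by 60-200
#' steps/min against 40-220 beats/min; out-of-range mass is collected in
#' underflow/overflow bins by the distribution functions.
#'
#' @param lo,hi support bounds. @param width bin width (ratio units).
#' @return numeric vector of bin edges.
#' @export
clc_bins <- function(lo = 0.3, hi = 3.0, width = 0.01) {
  seq(lo, hi, by = width)
}

# counts of sorted values strictly below / at-or-below each x
count_lt <- function(x, sorted) findInterval(x, sorted, left.open = TRUE)
count_le <- function(x, sorted) findInterval(x, sorted)

# Exact CDF of R_sim at r: (1/N^2) * sum_h #{s <= r * h}, evaluated for a
# vector of r in chunks to bound the outer-product size.
null_cdf_impl <- function(r, hr, sorted_sr, counter) {
  n2 <- length(hr) * length(sorted_sr)
  out <- numeric(length(r))
  chunk <- max(1L, floor(4e6 / length(hr)))
  for (i in seq(1L, length(r), by = chunk)) {
    j <- i:min(i + chunk - 1L, length(r))
    m <- matrix(counter(as.vector(outer(hr, r[j])), sorted_sr), nrow = length(hr))
    out[j] <- colSums(m) / n2
  }
  out
}

null_cdf <- function(r, hr, sorted_sr) {
  null_cdf_impl(r, hr, sorted_sr, count_le)
}

# CDF just below r (strict inequality), needed for KS jumps and quantiles
null_cdf_left <- function(r, hr, sorted_sr) {
  null_cdf_impl(r, hr, sorted_sr, count_lt)
}

# Smallest r with F(r) >= q, located by bisection on the discrete CDF.
null_quantile <- function(q, hr, sorted_sr, iter = 90) {
  lo <- min(sorted_sr) / max(hr)
  hi <- max(sorted_sr) / min(hr)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (null_cdf(mid, hr, sorted_sr) >= q) hi <- mid else lo <- mid
  }
  hi
}

null_histogram <- function(hr, sorted_sr, edges) {
  n2 <- length(hr) * length(sorted_sr)
  cnt <- rowSums(matrix(
    count_lt(as.vector(outer(edges, hr)), sorted_sr),
    nrow = length(edges)
  ))
  tibble(
    bin_left = c(-Inf, edges),
    bin_right = c(edges, Inf),
    probability = c(cnt[1], diff(cnt), n2 - cnt[length(edges)]) / n2
  )
}

new_clc_distribution <- function(histogram, p_clc, p_weak_or_clc, q, skewness,
                                 method, n_hr, n_sr, extra = list()) {
  structure(
    c(
      list(
        histogram = histogram,
        p_clc = p_clc,
        p_weak_or_clc = p_weak_or_clc,
        median = q[2], iqr = q[3] - q[1], q25 = q[1], q75 = q[3],
        skewness = skewness,
        method = method, n_hr = n_hr, n_sr = n_sr
      ),
      extra
    ),
    class = "clc_distribution"
  )
}

#' Exact random-pairing null distribution of R_sim
#'
#' Computes, without sampling, the distribution of `R_sim = sr/hr` over all
#' `N x N` random pairings of a subject's post-filter heart-rate and
#' step-rate values: 1%-bin histogram, the probabilities of landing in the
#' CLC band (deviation <= `clc_threshold`) and the combined CLC + weak band
#' (deviation <= `weak_threshold`), and median/IQR/skewness of `R_sim`.
#' Quantiles come from bisection on the exact pairing CDF; skewness is the
#' exact standardized third moment, using that `E[R^k] = E[sr^k] E[hr^-k]`
#' under independent pairing.
#'
#' @param hr,sr numeric vectors of a subject's post-filter minute heart
#'   rates and step rates (each length >= 2; `hr > 0`).
#' @param edges histogram bin edges, from [clc_bins()].
#' @param clc_threshold,weak_threshold deviation bands (as in
#'   [classify_coupling()]).
#' @return object of class `clc_distribution` with `method = "exact"`.
#' @export
null_exact <- function(hr, sr, edges = clc_bins(),
                       clc_threshold = 0.01, weak_threshold = 0.10) {
  if (length(hr) < 2 || length(sr) < 2) {
    abort("need at least two heart-rate and two step-rate values")
  }
  if (any(hr <= 0)) abort("heart rate must be positive")
  sorted_sr <- sort(sr)
  n2 <- length(hr) * length(sr)

  band_prob <- function(band) {
    (sum(count_le((1 + band) * hr, sorted_sr)) -
      sum(count_lt((1 - band) * hr, sorted_sr))) / n2
  }

  m1 <- mean(sr) * mean(1 / hr)
  m2 <- mean(sr^2) * mean(1 / hr^2)
  m3 <- mean(sr^3) * mean(1 / hr^3)
  v <- m2 - m1^2
  skew <- if (v > 0) (m3 - 3 * m1 * m2 + 2 * m1^3) / v^1.5 else NA_real_

  new_clc_distribution(
    histogram = null_histogram(hr, sorted_sr, edges),
    p_clc = band_prob(clc_threshold),
    p_weak_or_clc = band_prob(weak_threshold),
    q = vapply(c(0.25, 0.5, 0.75), null_quantile, numeric(1),
      hr = hr, sorted_sr = sorted_sr
    ),
    skewness = skew,
    method = "exact", n_hr = length(hr), n_sr = length(sr),
    extra = list(hr = hr, sr = sr)
  )
}

#' Monte Carlo random-pairing null distribution of R_sim
#'
#' Draws `n_samples` index pairs uniformly with replacement and summarises
#' the sampled `R_sim` values; converges to [null_exact()] as `n_samples`
#' grows. Kept for fidelity with Monte Carlo practice and for sample-based
#' summaries; the exact method is the default elsewhere.
#'
#' @inheritParams null_exact
#' @param n_samples number of sampled pairs (>= 10000).
#' @param seed integer seed for the draw.
#' @return object of class `clc_distribution` with `method = "sampled"` and
#'   the draws in `$draws`.
#' @export
null_sampled <- function(hr, sr, n_samples = 1e5, seed = 1,
                         edges = clc_bins(),
                         clc_threshold = 0.01, weak_threshold = 0.10) {
  if (length(hr) < 1 || length(sr) < 1) abort("empty input")
  if (n_samples < 1e4) abort("`n_samples` must be at least 10,000")
  draws <- withr::with_seed(seed, {
    sr[sample.int(length(sr), n_samples, replace = TRUE)] /
      hr[sample.int(length(hr), n_samples, replace = TRUE)]
  })
  summarise_values(draws, edges, clc_threshold, weak_threshold,
    method = "sampled",
    extra = list(draws = draws, n_samples = n_samples, seed = seed),
    n_hr = length(hr), n_sr = length(sr)
  )
}

summarise_values <- function(values, edges, clc_threshold, weak_threshold,
                             method, extra, n_hr = NA_integer_,
                             n_sr = NA_integer_) {
  dev <- abs(values - 1)
  cnt <- count_lt(edges, sort(values))
  histogram <- tibble(
    bin_left = c(-Inf, edges),
    bin_right = c(edges, Inf),
    probability = c(cnt[1], diff(cnt), length(values) - cnt[length(edges)]) /
      length(values)
  )
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 1)
  new_clc_distribution(
    histogram = histogram,
    p_clc = mean(dev <= clc_threshold),
    p_weak_or_clc = mean(dev <= weak_threshold),
    q = q,
    skewness = skewness_sample(values),
    method = method, n_hr = n_hr, n_sr = n_sr,
    extra = extra
  )
}

#' Summarise the observed coupling-ratio distribution
#'
#' Same histogram grid and summaries as the null distributions, computed on
#' the observed per-minute ratios, plus the peak bin and its probability.
#' Band probabilities are the empirical coupling-class proportions.
#'
#' @param instances classified instances from [classify_coupling()], or a
#'   numeric vector of ratios.
#' @inheritParams null_exact
#' @return object of class `clc_distribution` with `method = "observed"`,
#'   observed ratios in `$values`, and `$peak_bin` / `$peak_probability`.
#' @export
observed_distribution <- function(instances, edges = clc_bins(),
                                  clc_threshold = 0.01, weak_threshold = 0.10) {
  values <- if (is.numeric(instances)) instances else instances$ratio
  if (length(values) < 2) abort("need at least two observed ratios")
  out <- summarise_values(values, edges, clc_threshold, weak_threshold,
    method = "observed", extra = list(values = values)
  )
  interior <- out$histogram[is.finite(out$histogram$bin_left), ]
  peak <- which.max(interior$probability)
  out$peak_bin <- c(interior$bin_left[peak], interior$bin_right[peak])
  out$peak_probability <- interior$probability[peak]
  out
}

#' @export
print.clc_distribution <- function(x, ...) {
  cat(sprintf(
    "<clc_distribution: %s> p_clc %.4f, p_weak_or_clc %.4f, median %.3f, IQR %.3f, skewness %.3f\n",
    x$method, x$p_clc, x$p_weak_or_clc, x$median, x$iqr, x$skewness
  ))
  invisible(x)
}

#' @method tidy clc_distribution
#' @export
tidy.clc_distribution <- function(x, ...) {
  tibble(
    method = x$method, p_clc = x$p_clc, p_weak_or_clc = x$p_weak_or_clc,
    median = x$median, iqr = x$iqr, skewness = x$skewness
  )
}

# Asymptotic Kolmogorov distribution tail: P(sqrt(n) D > lambda)
kolmogorov_p <- function(lambda) {
  if (lambda < 0.2) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Compare an observed ratio distribution with its null
#'
#' Two-sample Kolmogorov-Smirnov when the null carries Monte Carlo draws;
#' against the exact pairing CDF (with proper handling of its jumps, and the
#' asymptotic Kolmogorov p-value) when the null is exact. Also reports
#' `delta_p`, the observed minus null probability of the combined CLC + weak
#' band, and the skewness and IQR of both distributions.
#'
#' @param observed a `clc_distribution` from [observed_distribution()].
#' @param null a `clc_distribution` from [null_exact()] or [null_sampled()].
#' @return one-row tibble of class `clc_comparison`: `ks_statistic`, `ks_p`,
#'   `delta_p`, `skewness_observed`, `skewness_null`, `iqr_observed`,
#'   `iqr_null`, `n_observed`.
#' @export
compare_distributions <- function(observed, null) {
  stopifnot(
    inherits(observed, "clc_distribution"),
    inherits(null, "clc_distribution"),
    observed$method == "observed"
  )
  if (!isTRUE(all.equal(observed$histogram$bin_left, null$histogram$bin_left))) {
    abort("observed and null distributions use different bin grids")
  }
  x <- sort(observed$values)
  n <- length(x)
  if (null$method == "sampled") {
    ks <- suppressWarnings(stats::ks.test(x, null$draws))
    d <- unname(ks$statistic)
    p <- ks$p.value
  } else {
    sorted_sr <- sort(null$sr)
    f_hi <- null_cdf(x, null$hr, sorted_sr)
    f_lo <- null_cdf_left(x, null$hr, sorted_sr)
    # sup|F_n - F| allowing for jumps of the discrete null CDF at the
    # observed values: compare F_n(x_i) with F(x_i) and F_n(x_i^-) with
    # F(x_i^-)
    d <- max(seq_len(n) / n - f_hi, f_lo - (seq_len(n) - 1) / n, 0)
    p <- kolmogorov_p((sqrt(n) + 0.12 + 0.11 / sqrt(n)) * d)
  }
  out <- tibble(
    ks_statistic = d,
    ks_p = p,
    delta_p = observed$p_weak_or_clc - null$p_weak_or_clc,
    skewness_observed = observed$skewness,
    skewness_null = null$skewness,
    iqr_observed = observed$iqr,
    iqr_null = null$iqr,
    n_observed = n
  )
  class(out) <- c("clc_comparison", class(out))
  out
}
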