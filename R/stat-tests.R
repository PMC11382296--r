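# Nonparametric tests and effect sizes operating on per-subject summaries.

new_clc_test <- function(method, statistic, p_value, effect_size = NA_real_,
                         effect_type = NA_character_, n = NA_integer_,
                         flagged = FALSE, note = NA_character_) {
  structure(
    list(
      method = method, statistic = statistic, p_value = p_value,
      effect_size = effect_size, effect_type = effect_type, n = n,
      flagged = flagged, note = note
    ),
    class = "clc_test"
  )
}

#' @export
print.clc_test <- function(x, ...) {
  cat(sprintf(
    "<clc_test> %s: statistic = %.4g, p = %.4g%s%s\n",
    x$method, x$statistic, x$p_value,
    if (!is.na(x$effect_size)) {
      sprintf(", %s = %.3f", x$effect_type, x$effect_size)
    } else {
      ""
    },
    if (x$flagged) sprintf(" [flagged: %s]", x$note) else ""
  ))
  invisible(x)
}

#' @method tidy clc_test
#' @export
tidy.clc_test <- function(x, ...) {
  tibble(
    method = x$method, statistic = x$statistic, p_value = x$p_value,
    effect_size = x$effect_size, effect_type = x$effect_type,
    n = x$n, flagged = x$flagged, note = x$note
  )
}

#' @method glance clc_test
#' @export
glance.clc_test <- function(x, ...) tidy(x)

#' Paired Wilcoxon signed-rank test with effect size r = |Z|/sqrt(N)
#'
#' Signed-rank statistic (sum of positive-difference ranks, zero differences
#' dropped, average ranks for ties) with the normal approximation including
#' continuity correction, so a standardized Z exists; the effect size is
#' `r = |Z| / sqrt(N)` with `N` the number of pairs supplied. All-zero
#' differences leave Z undefined and flag the result.
#'
#' @param x,y paired per-subject values, equal length >= 5.
#' @param continuity apply the 0.5 continuity correction.
#' @return a `clc_test` (statistic is the signed-rank V; `$z` holds Z).
#' @examples
#' wilcoxon_paired(c(5, 6, 7, 8, 9, 10), c(4, 5, 5, 9, 6, 8))
#' @export
wilcoxon_paired <- function(x, y, continuity = TRUE) {
  if (length(x) != length(y)) abort("`x` and `y` must be paired (equal length)")
  n_pairs <- length(x)
  if (n_pairs < 5) abort("need at least 5 pairs")
  d <- x - y
  d <- d[!is.na(d)]
  nz <- d != 0
  if (!any(nz)) {
    out <- new_clc_test("wilcoxon_signed_rank", NA_real_, NA_real_,
      n = n_pairs, flagged = TRUE, note = "all differences zero; Z undefined"
    )
    out$z <- NA_real_
    return(out)
  }
  d <- d[nz]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) {
    out <- new_clc_test("wilcoxon_signed_rank", v, NA_real_,
      n = n_pairs, flagged = TRUE, note = "degenerate rank variance"
    )
    out$z <- NA_real_
    return(out)
  }
  cc <- if (continuity) sign(v - mu) * 0.5 else 0
  z <- (v - mu - cc) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  out <- new_clc_test("wilcoxon_signed_rank", v, p,
    effect_size = abs(z) / sqrt(n_pairs), effect_type = "r", n = n_pairs
  )
  out$z <- z
  out
}

#' Kruskal-Wallis test with eta-squared effect size
#'
#' Rank-based one-way comparison across groups (tie-corrected H from
#' [stats::kruskal.test()]) with effect size `eta^2 = H / (N - 1)`, `N` the
#' total sample size. The `"n"` denominator variant (`H / N`) is available
#' for compatibility with analyses that normalise by the plain sample size.
#'
#' @param values numeric observations.
#' @param groups group labels, same length as `values`; at least 2 groups.
#' @param eta_denominator `"n_minus_1"` (default) or `"n"`.
#' @return a `clc_test` with `effect_type = "eta_squared"`.
#' @export
kruskal_wallis_groups <- function(values, groups,
                                  eta_denominator = c("n_minus_1", "n")) {
  eta_denominator <- match.arg(eta_denominator)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) abort("need at least 2 groups")
  if (any(tabulate(groups) == 0)) abort("every group must be non-empty")
  n <- length(values)
  if (n < 5) abort("need at least 5 observations in total")
  kt <- kruskal.test(values, groups)
  h <- unname(kt$statistic)
  denom <- if (eta_denominator == "n_minus_1") n - 1 else n
  eta <- h / denom
  new_clc_test("kruskal_wallis", h, kt$p.value,
    effect_size = eta, effect_type = "eta_squared", n = n
  )
}

#' Friedman test on a complete subjects-by-conditions matrix
#'
#' @param mat numeric matrix, rows = subjects (blocks), columns =
#'   conditions; must be complete (no imputation is attempted).
#' @return a `clc_test`.
#' @export
friedman_blocks <- function(mat) {
  mat <- as.matrix(mat)
  if (any(is.na(mat))) abort("the subjects x conditions matrix must be complete")
  if (ncol(mat) < 2) abort("need at least 2 conditions")
  if (nrow(mat) < 5) abort("need at least 5 subjects")
  if (all(mat == mat[, 1])) {
    # identical conditions within every block: no rank information at all,
    # the statistic is zero by construction (the tie-corrected form is 0/0)
    return(new_clc_test("friedman", 0, 1, n = nrow(mat),
      note = "all conditions identical within every block"
    ))
  }
  ft <- friedman.test(mat)
  new_clc_test("friedman", unname(ft$statistic), ft$p.value,
    n = nrow(mat)
  )
}

#' Chi-squared goodness-of-fit test of normality
#'
#' Bins the sample into `k` equal-probability classes under a normal
#' distribution with the sample mean and standard deviation, and compares
#' observed with expected counts (`df = k - 3`, accounting for the two
#' estimated moments). The result is flagged when fewer than 3 bins reach an
#' expected count of 5.
#'
#' @param x numeric sample.
#' @param k number of equal-probability bins; default
#'   `min(20, max(4, floor(n/5)))`.
#' @return a `clc_test`.
#' @export
chisq_normality <- function(x, k = NULL) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) abort("need at least 8 observations")
  if (is.null(k)) k <- min(20, max(4, floor(n / 5)))
  m <- mean(x)
  s <- sd(x)
  if (s == 0) {
    return(new_clc_test("chisq_normality", NA_real_, NA_real_,
      n = n, flagged = TRUE, note = "zero variance"
    ))
  }
  breaks <- qnorm(seq_len(k - 1) / k, m, s)
  observed <- tabulate(findInterval(x, breaks) + 1L, nbins = k)
  expected <- rep(n / k, k)
  stat <- sum((observed - expected)^2 / expected)
  df <- k - 3
  flagged <- sum(expected >= 5) < 3 || df < 1
  new_clc_test("chisq_normality", stat,
    if (df >= 1) pchisq(stat, df, lower.tail = FALSE) else NA_real_,
    n = n, flagged = flagged,
    note = if (flagged) "too few well-filled bins for the chi-squared approximation" else NA_character_
  )
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors.
#' @return a `clc_test` with the correlation as `effect_size`
#'   (`effect_type = "pearson_r"`); the statistic is the t value.
#' @export
pearson_correlation <- function(x, y) {
  ct <- cor.test(x, y, method = "pearson")
  new_clc_test("pearson", unname(ct$statistic), ct$p.value,
    effect_size = unname(ct$estimate), effect_type = "pearson_r",
    n = length(x)
  )
}
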