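# Internal helpers shared across modules.

# Coupling classes ordered from strongest to weakest locking.
COUPLING_LEVELS <- c("CLC", "weak_CLC", "no_CLC")
INTENSITY_LEVELS <- c("light", "moderate", "vigorous")
GROUP_LEVELS <- c("most_vigorous", "most_moderate", "constant")

floor_minute <- function(x) lubridate::floor_date(x, "minute")

#' Assign coupling classes from deviations
#'
#' @param deviation numeric vector of |R - 1| values.
#' @param clc_threshold deviation at or below which a minute counts as CLC.
#' @param weak_threshold deviation at or below which a minute counts as at
#'   least weak CLC.
#' @return factor with levels CLC, weak_CLC, no_CLC.
#' @noRd
coupling_class_of <- function(deviation, clc_threshold = 0.01,
                              weak_threshold = 0.10) {
  stopifnot(clc_threshold < weak_threshold)
  # 1e-12 guard so decimal band edges behave as written (e.g. |99/100 - 1|
  # evaluates one ulp above 0.01 in binary floating point)
  eps <- 1e-12
  cls <- ifelse(deviation <= clc_threshold + eps, "CLC",
    ifelse(deviation <= weak_threshold + eps, "weak_CLC", "no_CLC")
  )
  factor(cls, levels = COUPLING_LEVELS)
}

intensity_class_of <- function(sr, cuts = c(60, 100, 130)) {
  stopifnot(length(cuts) == 3, !is.unsorted(cuts))
  if (any(sr < cuts[1])) {
    abort("step rates below the activity threshold cannot be assigned an intensity class")
  }
  cls <- ifelse(sr < cuts[2], "light", ifelse(sr < cuts[3], "moderate", "vigorous"))
  factor(cls, levels = INTENSITY_LEVELS)
}

# Sample skewness, adjusted Fisher-Pearson standardized third moment.
skewness_sample <- function(x) {
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(NA_real_)
  g1 <- mean((x - m)^3) / s2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

iqr_of <- function(x) unname(diff(quantile(x, c(0.25, 0.75), names = FALSE)))

# stable per-subject integer seed derived from a root seed
subject_seed <- function(seed, subject_index) {
  s <- as.integer(seed) + as.integer(subject_index)
  if (s >= .Machine$integer.max) s <- s %% .Machine$integer.max
  s
}
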