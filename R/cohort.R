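# Rank-based comparison of metric distributions between two independent
# cohorts (e.g. expert vs novice), and assessment of the bias introduced
# by letting the tracker run fully automatically instead of with manual
# verification.

#' Compare one metric between two independent groups
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test. The null distribution is
#' exact when the combined sample size is at most 20 and there are no
#' ties; otherwise the normal approximation with tie correction and
#' continuity correction is used. Group medians are reported alongside the
#' U statistic (computed for group A).
#'
#' @param valuesA,valuesB metric values for the two groups (each n >= 2).
#' @param metricName label carried into the result.
#' @param alpha significance level (default 0.05).
#' @return a \linkS4class{GroupComparison}.
#' @examples
#' compareGroups(c(1, 2, 3, 4, 5), c(6, 7, 8, 9, 10), "path_length_cm")
#' @export
compareGroups <- function(valuesA, valuesB, metricName = "metric",
                          alpha = 0.05) {
  valuesA <- as.numeric(valuesA); valuesB <- as.numeric(valuesB)
  if (length(valuesA) < 2L || length(valuesB) < 2L)
    .err("insufficient_data", "each group needs at least 2 values")
  hasTies <- anyDuplicated(c(valuesA, valuesB)) > 0L
  useExact <- (length(valuesA) + length(valuesB) <= 20L) && !hasTies
  wt <- suppressWarnings(
    stats::wilcox.test(valuesA, valuesB, alternative = "two.sided",
                       exact = useExact, correct = TRUE))
  p <- min(1, unname(wt$p.value))
  new("GroupComparison",
      metricName = metricName,
      medianA = stats::median(valuesA), medianB = stats::median(valuesB),
      statistic = unname(wt$statistic), pValue = p,
      nA = length(valuesA), nB = length(valuesB),
      significant = p < alpha,
      method = if (useExact) "exact rank-sum"
               else "normal approximation with tie correction")
}

#' Fully-automatic vs semi-automatic tracking bias
#'
#' For paired per-procedure metric values obtained with the tracker run
#' fully automatically (\code{auto}) and with manual verification
#' (\code{semi}), reports the relative difference (auto - semi)/semi per
#' pair, the median relative difference, and the pairs whose absolute
#' relative difference exceeds \code{outlierThreshold} (typically caused
#' by the wrong pixel being re-acquired after an occlusion).
#'
#' @param semi,auto paired metric values, same length >= 1.
#' @param outlierThreshold flag pairs with |relDiff| above this (default
#'   0.25, i.e. 25 percent).
#' @return a \linkS4class{BiasReport}.
#' @export
biasAssessment <- function(semi, auto, outlierThreshold = 0.25) {
  semi <- as.numeric(semi); auto <- as.numeric(auto)
  if (length(semi) != length(auto))
    .err("contract", "semi and auto must be paired (same length)")
  if (length(semi) < 1L)
    .err("contract", "at least one pair is required")
  rel <- rep(NA_real_, length(semi))
  usable <- semi != 0
  if (any(!usable))
    .warn("zero_reference",
          sprintf("%d pair(s) with semi value 0 skipped", sum(!usable)))
  rel[usable] <- (auto[usable] - semi[usable]) / semi[usable]
  tab <- data.frame(index = seq_along(semi), semi = semi, auto = auto,
                    relDiff = rel,
                    outlier = !is.na(rel) & abs(rel) > outlierThreshold)
  new("BiasReport", table = tab,
      medianRelDiff = stats::median(rel, na.rm = TRUE),
      outlierThreshold = outlierThreshold)
}

#' Five-number summary by the median-of-halves convention
#'
#' Minimum, lower quartile, median, upper quartile and maximum, with
#' quartiles computed as the medians of the lower and upper halves of the
#' sorted data (the median itself is excluded from both halves when n is
#' odd). This is the convention of classic box-and-whisker construction
#' and is stated here for reproducibility; it differs from
#' \code{stats::fivenum}'s hinges for some n.
#'
#' @param values numeric vector, length >= 1.
#' @return named numeric vector \code{(min, q1, median, q3, max)}.
#' @examples
#' summaryBoxstats(1:9)  # 1, 2.5, 5, 7.5, 9
#' @export
summaryBoxstats <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values))
    .err("contract", "values must be non-empty and free of NA")
  s <- sort(values)
  n <- length(s)
  if (n == 1L)
    return(c(min = s, q1 = s, median = s, q3 = s, max = s))
  half <- floor(n / 2)
  lower <- s[seq_len(half)]
  upper <- s[(n - half + 1L):n]
  c(min = s[1L], q1 = stats::median(lower), median = stats::median(s),
    q3 = stats::median(upper), max = s[n])
}
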