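#' Total-count normalization factor between two libraries
#'
#' The ratio of the two library totals; multiplying every count of the
#' second (denominator) group by it equalises the totals exactly.  Computed
#' once from the non-chloroplast stream totals (no threshold) and applied
#' to all counts of the denominator group.
#'
#' @param totalA,totalB library totals (numerator / denominator group).
#' @return a [NormalizationFactor].
#' @export
normalizationFactor <- function(totalA, totalB) {
  if (totalA <= 0 || totalB <= 0) stop("library totals must be positive")
  new("NormalizationFactor", value = totalA / totalB,
      numeratorTotal = as.numeric(totalA), denominatorTotal = as.numeric(totalB))
}

#' Scale counts by a normalization factor
#'
#' @param count raw counts of the denominator group (vectorised).
#' @param factor a [NormalizationFactor] or a plain positive number.
#' @return normalized counts at full double precision.
#' @export
normalizeCount <- function(count, factor) {
  if (is(factor, "NormalizationFactor")) factor <- factor@value
  if (any(count < 0)) stop("counts must be non-negative")
  count * factor
}

#' log2 expression ratio with zero-count sentinel
#'
#' `log2(normalizedB / countA)` where both sides are positive; `NA`
#' otherwise (the feature is then reported as group-specific rather than
#' pseudocounted).  Features absent from both groups trigger a warning.
#'
#' @param countA raw counts of the numerator (reference) group.
#' @param normalizedB normalized counts of the other group.
#' @return numeric vector; `NA` marks undefined ratios.
#' @export
log2Ratio <- function(countA, normalizedB) {
  if (any(countA == 0 & normalizedB == 0))
    warning("feature with zero counts in both groups dropped from log2")
  ifelse(countA > 0 & normalizedB > 0, log2(normalizedB / countA), NA_real_)
}

#' Classify features by group specificity and fold change
#'
#' @param countA,countB raw counts in the two groups.
#' @param factor normalization factor applied to group B.
#' @param log2Threshold absolute log2 ratio at or above which a shared
#'   feature is differentially expressed.
#' @return factor with levels `A-specific`, `B-specific`, `common-DE-up`
#'   (higher in B), `common-DE-down`, `common-flat`.
#' @export
deClassify <- function(countA, countB, factor, log2Threshold = 1) {
  lr <- log2Ratio(countA, normalizeCount(countB, factor))
  cls <- ifelse(countA > 0 & countB == 0, "A-specific",
         ifelse(countA == 0 & countB > 0, "B-specific",
         ifelse(lr >= log2Threshold, "common-DE-up",
         ifelse(lr <= -log2Threshold, "common-DE-down", "common-flat"))))
  factor(cls, levels = c("A-specific", "B-specific", "common-DE-up",
                         "common-DE-down", "common-flat"))
}

#' Feature table with normalized counts and log2 ratios
#'
#' The per-feature comparison table: raw counts, normalized second-group
#' count, log2 ratio (NA printed as the `#NUM!` convention by the TSV
#' writer) and the group-specificity/DE class.
#'
#' @param features data.frame with at least `feature`, `countA`, `countB`.
#' @param factor a [NormalizationFactor].
#' @param log2Threshold |log2| cut classifying shared features as DE.
#' @return the input plus `normalizedB`, `log2`, `class` columns.
#' @export
diffexpTable <- function(features, factor, log2Threshold = 1) {
  features$normalizedB <- normalizeCount(features$countB, factor)
  features$log2 <- suppressWarnings(log2Ratio(features$countA,
                                              features$normalizedB))
  features$class <- suppressWarnings(
    deClassify(features$countA, features$countB, factor, log2Threshold))
  features
}

#' Threshold accounting of two read populations
#'
#' Reproduces the published group-comparison accounting per read-count
#' threshold t: per-group unique reads (count >= t) and their summed
#' counts, group-specific reads (count >= t in one group, absent from the
#' other), shared ("common") reads — present in both groups with summed
#' count >= t — and, among those, the reads whose normalized |log2| ratio
#' reaches `log2Threshold`, split by direction, with the DE percentage.
#' Ratio columns mirror the published table (control / transgenic).
#'
#' @param reads a [UniqueReadSet] with exactly two groups (first = control
#'   / numerator).
#' @param thresholds integer read-count thresholds (>= 1).
#' @param factor a [NormalizationFactor]; by default computed from this
#'   stream's two totals.  Pass the non-chloroplast factor to reproduce the
#'   published convention of one global factor.
#' @param log2Threshold |log2| >= this marks differential expression.
#' @return data.frame, one row per threshold, columns as in the published
#'   statistics table.
#' @export
summarizeGroups <- function(reads, thresholds = c(1L, 4L, 10L), factor = NULL,
                            log2Threshold = 1) {
  if (any(thresholds < 1L)) stop("thresholds must be >= 1")
  cnt <- readCounts(reads)
  stopifnot(ncol(cnt) == 2L)
  a <- cnt[, 1L]; b <- cnt[, 2L]
  if (is.null(factor)) factor <- normalizationFactor(sum(a), sum(b))
  lr <- suppressWarnings(log2Ratio(a, normalizeCount(b, factor)))
  out <- list()
  for (t in sort(thresholds)) {
    specA <- a >= t & b == 0L
    specB <- b >= t & a == 0L
    common <- a > 0L & b > 0L & (a + b) >= t
    deA <- common & !is.na(lr) & lr <= -log2Threshold
    deB <- common & !is.na(lr) & lr >= log2Threshold
    out[[as.character(t)]] <- data.frame(
      threshold = t,
      unique_ctrl = sum(a >= t), unique_tg = sum(b >= t),
      unique_fraction = sum(a >= t) / sum(b >= t),
      count_ctrl = sum(a[a >= t]), count_tg = sum(b[b >= t]),
      count_fraction = sum(a[a >= t]) / sum(b[b >= t]),
      specific_ctrl = sum(specA), specific_tg = sum(specB),
      specific_fraction = sum(specA) / sum(specB),
      common = sum(common),
      de_ctrl = sum(deA), de_tg = sum(deB), de_sum = sum(deA) + sum(deB),
      de_percent = 100 * (sum(deA) + sum(deB)) / sum(common))
  }
  `rownames<-`(do.call(rbind, out), NULL)
}
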