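#' Percentile threshold of an ancestry component
#'
#' Linear-interpolation (inclusive) percentile of the observed values —
#' the convention used to split a self-reported group at, e.g., the 80th
#' percentile of one ancestry component. Deterministic given the data.
#'
#' @param values numeric vector, non-empty.
#' @param pct percentile in \[0,100\] (default 80).
#' @return numeric scalar within the observed range.
#' @examples
#' percentileThreshold(c(0.1, 0.2, 0.3, 0.4, 0.5))  # 0.42
#' @export
percentileThreshold <- function(values, pct = 80) {
  if (!length(values)) stop("empty vector: percentile undefined")
  stopifnot(pct >= 0, pct <= 100, !anyNA(values))
  unname(stats::quantile(values, pct / 100, type = 7))
}

#' Carrier rates above and below an ancestry-percentile threshold
#'
#' Splits a cohort at a threshold on one ancestry component (by default
#' the cohort's own `pct`-th percentile), computes the carrier rate
#' carriers / (carriers + non-carriers) in the low stratum (ancestry <=
#' threshold) and the high stratum (> threshold), and tests the 2x2
#' carrier-by-stratum table with a two-sided Fisher's exact test.
#'
#' @param ancestry numeric vector, one ancestry proportion per sample.
#' @param carrier logical vector, carrier status per sample (untested
#'   samples must be removed beforehand).
#' @param pct percentile defining the threshold (default 80); ignored
#'   when `threshold` is given.
#' @param threshold optional explicit threshold overriding the
#'   percentile.
#' @return list with `threshold`, per-stratum counts
#'   (`carriers_below`, `non_carriers_below`, `carriers_above`,
#'   `non_carriers_above`), `rate_below`, `rate_above` (NA with a
#'   warning for an empty stratum) and the Fisher `p_value`.
#' @export
carrierRateSplit <- function(ancestry, carrier, pct = 80, threshold = NULL) {
  stopifnot(length(ancestry) == length(carrier), is.logical(carrier),
            !anyNA(ancestry), !anyNA(carrier))
  if (is.null(threshold)) threshold <- percentileThreshold(ancestry, pct)
  lo <- ancestry <= threshold
  k <- c(carriers_below     = sum(carrier & lo),
         non_carriers_below = sum(!carrier & lo),
         carriers_above     = sum(carrier & !lo),
         non_carriers_above = sum(!carrier & !lo))
  n_lo <- k[1] + k[2]; n_hi <- k[3] + k[4]
  if (n_lo == 0 || n_hi == 0) warning("empty stratum; rate undefined")
  p <- stats::fisher.test(matrix(k, 2, 2))$p.value
  list(threshold = threshold,
       counts = as.list(k),
       rate_below = if (n_lo > 0) unname(k[1] / n_lo) else NA_real_,
       rate_above = if (n_hi > 0) unname(k[3] / n_hi) else NA_real_,
       p_value = p)
}

#' Compare an ancestry component between carriers and non-carriers
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test of the ancestry
#' proportion between carriers and non-carriers, with the group means.
#' The exact null distribution is used for small groups (min group size
#' <= 8, no ties); otherwise the tie-corrected normal approximation.
#'
#' @param carrierQ numeric, ancestry proportions of carriers (non-empty).
#' @param noncarrierQ numeric, ancestry proportions of non-carriers
#'   (non-empty).
#' @return list with `p_value`, `U` (statistic for the carrier group),
#'   `mean_carrier`, `mean_noncarrier`, and `method` ("exact" or
#'   "normal").
#' @export
ancestryByCarrierTest <- function(carrierQ, noncarrierQ) {
  if (!length(carrierQ) || !length(noncarrierQ))
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(carrierQ, noncarrierQ)) > 0
  exact <- min(length(carrierQ), length(noncarrierQ)) <= 8 && !ties
  wt <- stats::wilcox.test(carrierQ, noncarrierQ, exact = exact,
                           correct = !exact)
  list(p_value = wt$p.value,
       U = unname(wt$statistic),
       mean_carrier = mean(carrierQ),
       mean_noncarrier = mean(noncarrierQ),
       method = if (exact) "exact" else "normal")
}

#' Residual carrier risk after a negative screen
#'
#' Bayes' rule for a screening panel that detects a fraction `d` of true
#' carriers in a population with carrier rate `c`: after a negative
#' result the posterior probability of still being a carrier is
#' risk = c (1 - d) / (1 - c d), conventionally reported as
#' "1 in N" with N = round(1 / risk) (half-up).
#'
#' @param carrierRate prior carrier rate `c` in \[0,1).
#' @param detectionRate panel detection rate `d` in \[0,1\].
#' @return list with `risk` (posterior probability) and `denominator`
#'   (N; `Inf` when risk is 0).
#' @examples
#' residualRisk(0.01606, 0.72)  # 1 in 220
#' residualRisk(0.037, 0.72)    # 1 in 94
#' @export
residualRisk <- function(carrierRate, detectionRate) {
  stopifnot(carrierRate >= 0, carrierRate <= 1,
            detectionRate >= 0, detectionRate <= 1)
  if (carrierRate == 1 && detectionRate == 1)
    stop("degenerate input: all carriers, perfect detection")
  risk <- carrierRate * (1 - detectionRate) / (1 - carrierRate * detectionRate)
  list(risk = risk,
       denominator = if (risk > 0) roundHalfUp(1 / risk) else Inf)
}
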