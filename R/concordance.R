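# round half away from zero, matching clinical table formatting
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Paired self-report concordance counts per ethnicity label
#'
#' For each controlled ethnicity label, counts how many samples selected
#' it on the requisition form (`n_form`), reported it during the genetic
#' counseling consult (`n_consult`), and did both (`n_both`), plus the
#' discordant counts `b = n_form - n_both` (form only) and
#' `c = n_consult - n_both` (consult only). Restricted to samples that
#' have a consult record; samples flagged excluded (bare "Other" with no
#' clarification) are dropped. A sample contributes to every label it
#' reported (the forms are check-all-that-apply).
#'
#' @param meta sample metadata as returned by [readSampleMetadata()] (or
#'   [simulateMetadata()]).
#' @param labels labels to tabulate; defaults to every label observed in
#'   either source.
#' @return data.frame with columns `ethnicity`, `n_form`, `n_consult`,
#'   `n_both`, `b`, `c`, plus an attribute `n_samples` (cohort size after
#'   exclusions).
#' @export
buildConcordance <- function(meta, labels = NULL) {
  keep <- meta$has_consult & !meta$excluded
  meta <- meta[keep, , drop = FALSE]
  if (is.null(labels)) {
    labels <- sort(unique(c(unlist(meta$form), unlist(meta$consult))))
  }
  n <- nrow(meta)
  out <- data.frame(ethnicity = labels,
                    n_form = 0L, n_consult = 0L, n_both = 0L)
  for (j in seq_along(labels)) {
    lf <- vapply(meta$form, function(s) labels[j] %in% s, TRUE)
    lc <- vapply(meta$consult, function(s) labels[j] %in% s, TRUE)
    out$n_form[j] <- sum(lf)
    out$n_consult[j] <- sum(lc)
    out$n_both[j] <- sum(lf & lc)
  }
  out$b <- out$n_form - out$n_both
  out$c <- out$n_consult - out$n_both
  attr(out, "n_samples") <- n
  out
}

#' Overlap percentages between the two self-report sources
#'
#' For a label with counts (n_form, n_consult, n_both), the fraction of
#' form reporters confirmed in consult, 100 n_both / n_form, and the
#' fraction of consult reporters who had selected the label on the form,
#' 100 n_both / n_consult. Percentages are rounded half-up to one
#' decimal, the convention of clinical summary tables.
#'
#' @param nForm,nConsult,nBoth the count triple (vectors allowed).
#' @return data.frame with `pct_form_in_consult` and
#'   `pct_consult_in_form`; a zero denominator yields `NA` and a warning.
#' @examples
#' overlapPercentages(206, 200, 191)  # 92.7, 95.5
#' @export
overlapPercentages <- function(nForm, nConsult, nBoth) {
  stopifnot(all(nBoth <= pmin(nForm, nConsult)))
  if (any(nForm == 0 | nConsult == 0))
    warning("zero denominator; overlap percentage undefined")
  data.frame(
    pct_form_in_consult = ifelse(nForm > 0,
                                 roundHalfUp(100 * nBoth / nForm, 1), NA_real_),
    pct_consult_in_form = ifelse(nConsult > 0,
                                 roundHalfUp(100 * nBoth / nConsult, 1), NA_real_))
}

#' Exact McNemar test on paired discordant counts
#'
#' Tests marginal homogeneity of two paired binary reports from the
#' discordant counts alone: under the null the b form-only and c
#' consult-only samples are Binomial(b + c, 1/2). The default two-sided
#' p-value doubles the smaller tail and caps at 1,
#' p = min(1, 2 sum_\{k <= min(b,c)\} C(n,k) 2^\{-n\}), evaluated in
#' log-space so extreme imbalances (p ~ 1e-64) do not underflow. The
#' `"minlike"` alternative instead sums all outcomes no more likely than
#' the observed one. With no discordant pairs the test is vacuous and
#' p = 1.
#'
#' @param b count discordant in one direction (form only).
#' @param c count discordant in the other (consult only).
#' @param twoSided `"double"` (default) or `"minlike"`.
#' @return two-sided p-value in (0, 1\].
#' @examples
#' mcnemarExact(14, 276)  # 2.63e-64
#' @export
mcnemarExact <- function(b, c, twoSided = c("double", "minlike")) {
  twoSided <- match.arg(twoSided)
  stopifnot(length(b) == 1, length(c) == 1, b >= 0, c >= 0,
            b == as.integer(b), c == as.integer(c))
  n <- b + c
  if (n == 0) return(1)
  if (twoSided == "double") {
    min(1, 2 * exp(stats::pbinom(min(b, c), n, 0.5, log.p = TRUE)))
  } else {
    ld <- stats::dbinom(0:n, n, 0.5, log = TRUE)
    sum(exp(ld[ld <= ld[b + 1L] + 1e-7]))
  }
}

#' Full concordance table with percentages and McNemar p-values
#'
#' Convenience wrapper combining [buildConcordance()],
#' [overlapPercentages()] and [mcnemarExact()] into one table, one row
#' per ethnicity label.
#'
#' @inheritParams buildConcordance
#' @return data.frame with counts, both overlap percentages and the
#'   exact McNemar p-value per label.
#' @export
concordanceTable <- function(meta, labels = NULL) {
  tab <- buildConcordance(meta, labels)
  pct <- overlapPercentages(tab$n_form, tab$n_consult, tab$n_both)
  tab$pct_form_in_consult <- pct$pct_form_in_consult
  tab$pct_consult_in_form <- pct$pct_consult_in_form
  tab$p_value <- vapply(seq_len(nrow(tab)),
                        function(i) mcnemarExact(tab$b[i], tab$c[i]), 0)
  tab
}
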