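#' @import methods
NULL

VALID_DOSAGES <- c(0L, 1L, 2L)

#' Genotype dosage matrix
#'
#' Stores biallelic SNP genotypes as counts of a designated "allele 1" per
#' marker. Rows are markers, columns are samples; entries are 0, 1, 2 or
#' `NA` (no call). `NA` is the only missing representation — missing calls
#' are never zero-filled, because a silent zero would bias downstream
#' ancestry estimates toward populations where allele 1 is rare.
#'
#' @slot dosage integer matrix, markers x samples, values in \{0,1,2,NA\};
#'   dimnames hold marker and sample identifiers.
#' @slot allele1 character vector, the counted allele per marker (for VCF
#'   input this is the ALT allele).
#' @slot allele2 character vector, the other allele per marker; may be `NA`
#'   when the source format does not record it (plain dosage TSV).
#'
#' @seealso [readGenotypes()], [harmonizeAlleles()]
#' @export
setClass("GenotypeMatrix",
  representation(
    dosage  = "matrix",
    allele1 = "character",
    allele2 = "character"
  )
)

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosage
  msg <- character()
  if (!is.integer(d)) msg <- c(msg, "dosage must be an integer matrix")
  if (is.null(rownames(d)) || is.null(colnames(d)))
    msg <- c(msg, "dosage must carry marker (row) and sample (column) names")
  else {
    if (anyDuplicated(rownames(d))) msg <- c(msg, "marker ids must be unique")
    if (anyDuplicated(colnames(d))) msg <- c(msg, "sample ids must be unique")
  }
  bad <- d[!is.na(d)]
  if (length(bad) && !all(bad %in% VALID_DOSAGES))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (length(object@allele1) != nrow(d))
    msg <- c(msg, "allele1 must have one entry per marker")
  if (anyNA(object@allele1))
    msg <- c(msg, "allele1 must be defined for every marker")
  if (length(object@allele2) != nrow(d))
    msg <- c(msg, "allele2 must have one entry per marker")
  if (length(msg)) msg else TRUE
})

#' Population allele-frequency panel
#'
#' Allele-1 frequencies per reference population x marker. Populations may
#' carry a continental-group label so that population-level panels can be
#' averaged into continental panels before marker selection.
#'
#' @slot freq numeric matrix, populations x markers, values in \[0,1\] or
#'   `NA` (missing before QC); dimnames hold population and marker ids.
#' @slot allele1 character, counted allele per marker.
#' @slot continentalGroup character, one label per population; `NA` when the
#'   panel is already at the continental level.
#'
#' @seealso [readFrequencyPanel()], [continentalFrequencies()]
#' @export
setClass("FrequencyPanel",
  representation(
    freq             = "matrix",
    allele1          = "character",
    continentalGroup = "character"
  )
)

setValidity("FrequencyPanel", function(object) {
  f <- object@freq
  msg <- character()
  if (!is.numeric(f)) msg <- c(msg, "freq must be a numeric matrix")
  if (is.null(rownames(f)) || is.null(colnames(f)))
    msg <- c(msg, "freq must carry population (row) and marker (column) names")
  else {
    if (anyDuplicated(rownames(f))) msg <- c(msg, "population ids must be unique")
    if (anyDuplicated(colnames(f))) msg <- c(msg, "marker ids must be unique")
  }
  obs <- f[!is.na(f)]
  if (length(obs) && (min(obs) < 0 || max(obs) > 1))
    msg <- c(msg, "frequencies must lie in [0, 1]")
  if (length(object@allele1) != ncol(f))
    msg <- c(msg, "allele1 must have one entry per marker")
  if (length(object@continentalGroup) != nrow(f))
    msg <- c(msg, "continentalGroup must have one entry per population")
  if (length(msg)) msg else TRUE
})

#' Per-sample ancestry estimates
#'
#' Result container for supervised admixture estimation: one ancestry
#' vector on the K-simplex per sample, with the final log-likelihood,
#' iteration count and convergence flag of each sample's EM run.
#'
#' @slot proportions numeric matrix, samples x populations; each row sums
#'   to 1 (rows of samples with no usable markers are `NA`).
#' @slot loglik numeric, final log-likelihood per sample.
#' @slot iterations integer, EM iterations per sample.
#' @slot converged logical, whether the stopping rule was met (NA when no
#'   estimate was possible).
#'
#' @seealso [estimateAncestry()], [maxAncestralGroup()]
#' @export
setClass("AncestryEstimate",
  representation(
    proportions = "matrix",
    loglik      = "numeric",
    iterations  = "integer",
    converged   = "logical"
  )
)

setValidity("AncestryEstimate", function(object) {
  p <- object@proportions
  msg <- character()
  if (is.null(rownames(p)) || is.null(colnames(p)))
    msg <- c(msg, "proportions must carry sample (row) and population (column) names")
  ok <- stats::complete.cases(p)
  if (any(ok)) {
    rs <- rowSums(p[ok, , drop = FALSE])
    if (any(abs(rs - 1) > 1e-9))
      msg <- c(msg, "each ancestry vector must sum to 1 within 1e-9")
    if (min(p[ok, ]) < -1e-12)
      msg <- c(msg, "ancestry proportions must be non-negative")
  }
  n <- nrow(p)
  if (length(object@loglik) != n || length(object@iterations) != n ||
      length(object@converged) != n)
    msg <- c(msg, "loglik, iterations and converged must have one entry per sample")
  if (length(msg)) msg else TRUE
})
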