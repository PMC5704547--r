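rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  x <- matrix(stats::rgamma(n * K, shape = alpha), n, K, byrow = TRUE)
  x / rowSums(x)
}

#' Simulate a population allele-frequency panel
#'
#' Draws each population-by-marker allele-1 frequency independently from
#' a Beta distribution. The default Beta(0.5, 0.5) is U-shaped, pushing
#' frequencies toward 0 and 1 as in a panel of ancestry-informative
#' markers, where between-population differentiation is high by
#' construction.
#'
#' @param K number of populations (default 6).
#' @param M number of markers (default 1142, a realistic
#'   ancestry-informative panel size).
#' @param freqBeta length-2 shape parameters of the Beta (default
#'   c(0.5, 0.5)).
#' @param populationIds population labels (default POP1..POPK); also
#'   used as continental group labels, one population per group.
#' @param seed optional RNG seed for reproducibility.
#' @return a complete [FrequencyPanel] (alleles A/B per marker).
#' @export
simulatePanel <- function(K = 6, M = 1142, freqBeta = c(0.5, 0.5),
                          populationIds = paste0("POP", seq_len(K)),
                          seed = NULL) {
  stopifnot(K >= 1, M >= 1, length(freqBeta) == 2, all(freqBeta > 0))
  if (!is.null(seed)) set.seed(seed)
  f <- matrix(stats::rbeta(K * M, freqBeta[1], freqBeta[2]), K, M,
              dimnames = list(populationIds,
                              sprintf("mk%05d", seq_len(M))))
  FrequencyPanel(f, allele1 = rep("A", M),
                 continentalGroup = populationIds)
}

#' Simulate an admixed genotype cohort under the mixture model
#'
#' Ancestry vectors Q are drawn from a symmetric Dirichlet; each
#' genotype is then Binomial(2, sum_k q_ik f_km) — exactly the
#' independent-allele mixture the supervised EM estimator assumes, so
#' parameter-recovery experiments against this generator are well-posed.
#' Missing calls are inserted completely at random at `missingRate`.
#'
#' @param panel a complete [FrequencyPanel].
#' @param n number of samples.
#' @param dirichletAlpha Dirichlet concentration: scalar (symmetric) or
#'   length-K. 1 gives uniformly admixed cohorts; 0.1 gives near-pure
#'   individuals.
#' @param missingRate fraction of calls set missing (default 0).
#' @param seed optional RNG seed.
#' @return list with `genotypes` (a [GenotypeMatrix], allele2 = "B") and
#'   `Q` (the true n x K ancestry matrix).
#' @export
simulateCohort <- function(panel, n, dirichletAlpha = 1, missingRate = 0,
                           seed = NULL) {
  stopifnot(is(panel, "FrequencyPanel"), n >= 1,
            missingRate >= 0, missingRate <= 1)
  f <- freq(panel)
  if (anyNA(f)) stop("panel must be complete")
  K <- nrow(f); M <- ncol(f)
  if (!is.null(seed)) set.seed(seed)
  alpha <- if (length(dirichletAlpha) == 1) rep(dirichletAlpha, K) else dirichletAlpha
  stopifnot(length(alpha) == K, all(alpha > 0))
  Q <- rdirichlet(n, alpha)
  dimnames(Q) <- list(sprintf("sample%04d", seq_len(n)), rownames(f))
  p <- Q %*% f                      # n x M mixture allele-1 frequency
  d <- matrix(stats::rbinom(n * M, 2L, p), n, M)
  if (missingRate > 0)
    d[stats::runif(n * M) < missingRate] <- NA_integer_
  gm <- GenotypeMatrix(t(d), allele1 = rep("A", M), allele2 = rep("B", M),
                       markerIds = colnames(f), sampleIds = rownames(Q))
  list(genotypes = gm, Q = Q)
}

#' Simulate self-report metadata and carrier flags from true ancestry
#'
#' Each sample's "true" label is its majority ancestry population. The
#' requisition-form and consult reports equal that label except that,
#' independently with probabilities `formNoise` and `consultNoise`, a
#' report is replaced by a different population label drawn uniformly; a
#' fraction `consultMissingRate` of samples lack a consult record
#' entirely. Carrier status for one disease follows a logistic link on
#' one ancestry component:
#' logit P(carrier) = logit(baselineCarrierRate) + carrierEffect * q_k.
#'
#' @param trueQ n x K ancestry matrix with population column names.
#' @param baselineCarrierRate carrier probability at q_k = 0
#'   (default 0.02).
#' @param carrierEffect slope on the carrier log-odds per unit ancestry
#'   proportion (default 0 = no association).
#' @param carrierComponent which ancestry column drives carrier risk
#'   (default 1).
#' @param formNoise,consultNoise label-replacement probabilities
#'   (default 0).
#' @param consultMissingRate fraction of samples without consult
#'   (default 0).
#' @param disease name of the simulated disease column.
#' @param seed optional RNG seed.
#' @return metadata data.frame in the layout of [readSampleMetadata()].
#' @export
simulateMetadata <- function(trueQ, baselineCarrierRate = 0.02,
                             carrierEffect = 0, carrierComponent = 1,
                             formNoise = 0, consultNoise = 0,
                             consultMissingRate = 0,
                             disease = "disease", seed = NULL) {
  stopifnot(is.matrix(trueQ), !is.null(colnames(trueQ)),
            baselineCarrierRate > 0, baselineCarrierRate < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(trueQ)
  labs <- colnames(trueQ)
  truth <- labs[max.col(trueQ, ties.method = "first")]
  relabel <- function(lab, rate) {
    flip <- stats::runif(n) < rate
    out <- lab
    if (any(flip) && length(labs) > 1)
      out[flip] <- vapply(lab[flip],
                          function(l) sample(setdiff(labs, l), 1), "")
    out
  }
  form <- relabel(truth, formNoise)
  consult <- relabel(truth, consultNoise)
  has_consult <- stats::runif(n) >= consultMissingRate
  p <- stats::plogis(stats::qlogis(baselineCarrierRate) +
                       carrierEffect * trueQ[, carrierComponent])
  carrier <- stats::runif(n) < p
  ids <- rownames(trueQ)
  if (is.null(ids)) ids <- sprintf("sample%04d", seq_len(n))
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  out$form <- as.list(form)
  cl <- vector("list", n)
  cl[has_consult] <- as.list(consult[has_consult])
  out$consult <- cl
  out$has_consult <- has_consult
  out$excluded <- FALSE
  out[[disease]] <- factor(ifelse(carrier, "carrier", "non-carrier"),
                           levels = c("carrier", "non-carrier", "untested"))
  attr(out, "diseases") <- disease
  attr(out, "true_label") <- truth
  out
}

#' Write simulated metadata as the standard CSV layout
#'
#' @param meta metadata data.frame ([simulateMetadata()] or
#'   [readSampleMetadata()] layout).
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeSampleMetadata <- function(meta, path) {
  diseases <- attr(meta, "diseases")
  join <- function(x) vapply(x, function(s) paste(s, collapse = ";"), "")
  tab <- data.frame(sample_id = meta$sample_id,
                    form_ethnicities = join(meta$form),
                    consult_ethnicities = ifelse(meta$has_consult,
                                                 join(meta$consult), ""),
                    check.names = FALSE)
  for (d in diseases) tab[[d]] <- as.character(meta[[d]])
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
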