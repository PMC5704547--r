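STRAND_AMBIGUOUS <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

isStrandAmbiguous <- function(a1, a2) {
  paste(a1, a2) %in% vapply(STRAND_AMBIGUOUS, paste, collapse = " ", "")
}

#' Harmonize the counted allele between genotypes and a frequency panel
#'
#' Restricts both objects to their shared markers and makes the genotype
#' dosages count the same allele the panel's frequencies refer to:
#'
#' * counted alleles already agree: marker kept as is;
#' * the panel counts the genotype's *other* allele: dosage flipped
#'   (g becomes 2-g) and the flip recorded;
#' * alleles cannot be reconciled (no match, unknown other allele, or an
#'   A/T / C/G strand-ambiguous marker whose counted alleles disagree —
#'   a flip there cannot be told apart from a strand difference): marker
#'   dropped with a warning.
#'
#' The operation is idempotent and returns both objects with identical
#' marker order.
#'
#' @param gm a [GenotypeMatrix].
#' @param fp a [FrequencyPanel].
#' @return list with elements `genotypes`, `panel`, and `flipped` (the
#'   marker ids whose dosages were complemented).
#' @export
harmonizeAlleles <- function(gm, fp) {
  stopifnot(is(gm, "GenotypeMatrix"), is(fp, "FrequencyPanel"))
  shared <- intersect(markerIds(gm), markerIds(fp))
  if (!length(shared)) stop("no shared markers between genotypes and panel")
  gm <- gm[shared, ]
  fp <- fp[, shared]
  g1 <- unname(allele1(gm)); g2 <- unname(allele2(gm))
  p1 <- unname(allele1(fp))
  same <- g1 == p1
  ambiguous <- !is.na(g2) & isStrandAmbiguous(g1, g2)
  flip <- !same & !is.na(g2) & g2 == p1 & !ambiguous
  keep <- same | flip
  if (!any(keep)) stop("no markers with reconcilable alleles")
  if (any(!keep))
    warning(sum(!keep), " marker(s) dropped (irreconcilable alleles): ",
            paste(utils::head(shared[!keep], 5), collapse = ", "))
  d <- dosage(gm)
  if (any(flip)) d[flip, ] <- 2L - d[flip, , drop = FALSE]
  a1 <- g1; a2 <- g2
  a1[flip] <- g2[flip]; a2[flip] <- g1[flip]
  out_gm <- GenotypeMatrix(d[keep, , drop = FALSE],
                           allele1 = a1[keep], allele2 = a2[keep])
  list(genotypes = out_gm,
       panel = fp[, which(keep)],
       flipped = shared[flip])
}
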