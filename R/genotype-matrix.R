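#' Construct a GenotypeMatrix
#'
#' @param dosage numeric/integer matrix of allele-1 copy counts
#'   (markers x samples); values 0, 1, 2 or NA. Row and column names are
#'   taken as marker and sample identifiers unless overridden.
#' @param allele1 character, counted allele per marker.
#' @param allele2 character, the other allele per marker; defaults to NA.
#' @param markerIds,sampleIds optional identifier vectors overriding the
#'   dimnames of `dosage`.
#' @return a [GenotypeMatrix].
#' @examples
#' gm <- GenotypeMatrix(matrix(c(0L, 1L, 2L, NA), 2, 2,
#'                             dimnames = list(c("rs1", "rs2"), c("s1", "s2"))),
#'                      allele1 = c("A", "G"))
#' dosage(gm)
#' @export
GenotypeMatrix <- function(dosage, allele1, allele2 = NULL,
                           markerIds = NULL, sampleIds = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (!is.null(markerIds)) rownames(dosage) <- markerIds
  if (!is.null(sampleIds)) colnames(dosage) <- sampleIds
  if (is.null(allele2)) allele2 <- rep(NA_character_, nrow(dosage))
  new("GenotypeMatrix",
      dosage = dosage,
      allele1 = as.character(allele1),
      allele2 = as.character(allele2))
}

#' @rdname GenotypeMatrix-class
#' @aliases markerIds,GenotypeMatrix-method
setMethod("markerIds", "GenotypeMatrix", function(x) rownames(x@dosage))

#' @rdname GenotypeMatrix-class
setMethod("sampleIds", "GenotypeMatrix", function(x) colnames(x@dosage))

#' @rdname GenotypeMatrix-class
setMethod("dosage", "GenotypeMatrix", function(x) x@dosage)

#' @rdname GenotypeMatrix-class
setMethod("allele1", "GenotypeMatrix", function(x) {
  stats::setNames(x@allele1, rownames(x@dosage))
})

#' @rdname GenotypeMatrix-class
setMethod("allele2", "GenotypeMatrix", function(x) {
  stats::setNames(x@allele2, rownames(x@dosage))
})

#' @rdname GenotypeMatrix-class
#' @param i marker index (id, position or logical).
#' @param j sample index.
#' @param drop ignored; subsetting always returns a `GenotypeMatrix`.
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosage))
  if (missing(j)) j <- seq_len(ncol(x@dosage))
  ii <- seq_len(nrow(x@dosage))
  names(ii) <- rownames(x@dosage)
  ii <- unname(ii[i])
  new("GenotypeMatrix",
      dosage = x@dosage[ii, j, drop = FALSE],
      allele1 = x@allele1[ii],
      allele2 = x@allele2[ii])
})

setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosage
  cat(sprintf("GenotypeMatrix: %d markers x %d samples\n", nrow(d), ncol(d)))
  miss <- mean(is.na(d))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  nshow <- min(5L, nrow(d))
  if (nshow > 0)
    cat("  markers:", paste(utils::head(rownames(d), nshow), collapse = ", "),
        if (nrow(d) > nshow) "..." else "", "\n")
})

#' Per-marker genotype call rate
#'
#' Fraction of samples with a non-missing call at each marker.
#'
#' @param gm a [GenotypeMatrix].
#' @return named numeric vector in \[0,1\].
#' @export
callRate <- function(gm) {
  stopifnot(is(gm, "GenotypeMatrix"))
  rowMeans(!is.na(gm@dosage))
}
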