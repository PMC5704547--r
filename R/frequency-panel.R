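#' Construct a FrequencyPanel
#'
#' @param freq numeric matrix of allele-1 frequencies
#'   (populations x markers), entries in \[0,1\] or NA.
#' @param allele1 character, counted allele per marker.
#' @param continentalGroup optional character, continental label per
#'   population (used by [continentalFrequencies()]).
#' @param populationIds,markerIds optional identifier vectors overriding
#'   the dimnames of `freq`.
#' @return a [FrequencyPanel].
#' @examples
#' fp <- FrequencyPanel(matrix(c(0.1, 0.9, 0.5, 0.4), 2, 2,
#'                             dimnames = list(c("YRI", "CEU"), c("rs1", "rs2"))),
#'                      allele1 = c("A", "G"),
#'                      continentalGroup = c("African", "European"))
#' freq(fp)
#' @export
FrequencyPanel <- function(freq, allele1, continentalGroup = NULL,
                           populationIds = NULL, markerIds = NULL) {
  freq <- as.matrix(freq)
  storage.mode(freq) <- "double"
  if (!is.null(populationIds)) rownames(freq) <- populationIds
  if (!is.null(markerIds)) colnames(freq) <- markerIds
  if (is.null(continentalGroup))
    continentalGroup <- rep(NA_character_, nrow(freq))
  new("FrequencyPanel",
      freq = freq,
      allele1 = as.character(allele1),
      continentalGroup = as.character(continentalGroup))
}

#' @rdname FrequencyPanel-class
setMethod("populationIds", "FrequencyPanel", function(x) rownames(x@freq))

#' @rdname FrequencyPanel-class
setMethod("markerIds", "FrequencyPanel", function(x) colnames(x@freq))

#' @rdname FrequencyPanel-class
setMethod("freq", "FrequencyPanel", function(x) x@freq)

#' @rdname FrequencyPanel-class
setMethod("allele1", "FrequencyPanel", function(x) {
  stats::setNames(x@allele1, colnames(x@freq))
})

#' @rdname FrequencyPanel-class
setMethod("continentalGroup", "FrequencyPanel", function(x) {
  stats::setNames(x@continentalGroup, rownames(x@freq))
})

#' @rdname FrequencyPanel-class
#' @param i population index.
#' @param j marker index.
#' @param drop ignored.
setMethod("[", "FrequencyPanel", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@freq))
  if (missing(j)) j <- seq_len(ncol(x@freq))
  pp <- seq_len(nrow(x@freq)); names(pp) <- rownames(x@freq)
  mm <- seq_len(ncol(x@freq)); names(mm) <- colnames(x@freq)
  pp <- unname(pp[i]); mm <- unname(mm[j])
  new("FrequencyPanel",
      freq = x@freq[pp, mm, drop = FALSE],
      allele1 = x@allele1[mm],
      continentalGroup = x@continentalGroup[pp])
})

setMethod("show", "FrequencyPanel", function(object) {
  f <- object@freq
  cat(sprintf("FrequencyPanel: %d populations x %d markers\n", nrow(f), ncol(f)))
  grp <- object@continentalGroup
  if (!all(is.na(grp)))
    cat("  continental groups:", paste(unique(grp[!is.na(grp)]), collapse = ", "), "\n")
  if (anyNA(f))
    cat(sprintf("  missing frequencies: %.2f%%\n", 100 * mean(is.na(f))))
  cat("  populations:", paste(utils::head(rownames(f), 6),
                              collapse = ", "),
      if (nrow(f) > 6) "..." else "", "\n")
})
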