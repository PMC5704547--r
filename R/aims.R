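#' QC-filter a frequency panel and genotype matrix
#'
#' Applies the marker/population quality filters used before ancestry
#' marker selection:
#'
#' 1. reference populations whose frequency coverage (fraction of markers
#'    with a known frequency) is below `minPopulationCoverage` are
#'    dropped;
#' 2. markers whose genotype call rate is below `minCallRate` are
#'    dropped;
#' 3. markers still missing a frequency in any remaining population are
#'    dropped.
#'
#' Both objects are returned restricted to the surviving markers, in the
#' same order.
#'
#' @param fp a [FrequencyPanel] (harmonized with `gm`).
#' @param gm a [GenotypeMatrix].
#' @param minPopulationCoverage minimum per-population frequency coverage
#'   (default 0.90).
#' @param minCallRate minimum per-marker genotype call rate
#'   (default 0.999).
#' @return list with elements `panel` and `genotypes`.
#' @export
qcFilter <- function(fp, gm, minPopulationCoverage = 0.90,
                     minCallRate = 0.999) {
  stopifnot(is(fp, "FrequencyPanel"), is(gm, "GenotypeMatrix"),
            minPopulationCoverage >= 0, minPopulationCoverage <= 1,
            minCallRate >= 0, minCallRate <= 1)
  if (!identical(markerIds(fp), markerIds(gm)))
    stop("panel and genotypes must be harmonized (identical marker order)")
  cov <- rowMeans(!is.na(freq(fp)))
  keep_pop <- cov >= minPopulationCoverage
  if (!any(keep_pop)) stop("all populations dropped by coverage filter")
  fp <- fp[which(keep_pop), ]
  keep_m <- callRate(gm) >= minCallRate & colSums(is.na(freq(fp))) == 0
  if (!any(keep_m)) stop("all markers dropped by QC")
  list(panel = fp[, which(keep_m)], genotypes = gm[which(keep_m), ])
}

#' Aggregate a population panel to continental-mean frequencies
#'
#' One output population per continental group; each frequency is the
#' unweighted arithmetic mean of the member populations' frequencies at
#' that marker.
#'
#' @param fp a [FrequencyPanel] whose every population carries a
#'   `continentalGroup` label.
#' @return a [FrequencyPanel] with one row per continental group (group
#'   label doubling as population id).
#' @export
continentalFrequencies <- function(fp) {
  stopifnot(is(fp, "FrequencyPanel"))
  grp <- unname(continentalGroup(fp))
  if (anyNA(grp)) stop("every population must carry a continental group label")
  groups <- unique(grp)
  f <- freq(fp)
  out <- matrix(NA_real_, length(groups), ncol(f),
                dimnames = list(groups, colnames(f)))
  for (g in groups) {
    members <- which(grp == g)
    if (!length(members)) stop("continental group with no members: ", g)
    out[g, ] <- colMeans(f[members, , drop = FALSE])
  }
  FrequencyPanel(out, allele1 = unname(allele1(fp)),
                 continentalGroup = groups)
}

#' Wright's Fst at a single marker
#'
#' Fixation index across groups from allele-1 frequencies, as the
#' proportional heterozygosity deficit (H_T - H_S)/H_T with the total
#' heterozygosity taken at the unweighted mean frequency:
#' p-bar = mean(p), H_T = 2 p-bar (1 - p-bar), H_S = mean(2 p (1 - p)).
#' Returns 0 for a monomorphic marker (H_T = 0). This is the Nei-style
#' G_ST on group means, appropriate when only frequency tables (no sample
#' counts) are available.
#'
#' @param freqs numeric vector of per-group allele-1 frequencies in
#'   \[0,1\], length >= 2.
#' @return Fst in \[0,1\].
#' @examples
#' wrightFst(c(1, 0))      # fixed difference: 1
#' wrightFst(c(0.2, 0.8))  # 0.36
#' @export
wrightFst <- function(freqs) {
  stopifnot(length(freqs) >= 2, all(freqs >= 0 & freqs <= 1))
  pbar <- mean(freqs)
  ht <- 2 * pbar * (1 - pbar)
  if (ht == 0) return(0)
  hs <- mean(2 * freqs * (1 - freqs))
  (ht - hs) / ht
}

# vectorized over the markers of a group x marker frequency matrix
fstAcrossMarkers <- function(f) {
  pbar <- colMeans(f)
  ht <- 2 * pbar * (1 - pbar)
  hs <- colMeans(2 * f * (1 - f))
  fst <- ifelse(ht == 0, 0, (ht - hs) / ht)
  pmin(pmax(fst, 0), 1)
}

#' LD pruning of markers by pairwise dosage correlation
#'
#' Greedy left-to-right pruning within a fixed-count sliding window, in
#' the style of plink's pairwise-independence command: markers must be in
#' genomic order; within each window, whenever a retained pair has
#' squared Pearson dosage correlation above `r2Threshold`, the later
#' marker of the pair is removed. Pairs with fewer than two complete
#' observations carry no evidence and are treated as r-squared 0.
#'
#' @param gm a [GenotypeMatrix] with markers in genomic order.
#' @param r2Threshold squared-correlation threshold (default 0.5).
#' @param windowSize window length in markers (default 1000).
#' @param step window advance in markers; default `windowSize %/% 10`
#'   (minimum 1).
#' @return character vector of retained marker ids, in input order.
#' @export
ldPrune <- function(gm, r2Threshold = 0.5, windowSize = 1000,
                    step = max(1L, windowSize %/% 10L)) {
  stopifnot(is(gm, "GenotypeMatrix"),
            r2Threshold > 0, r2Threshold <= 1, windowSize >= 2, step >= 1)
  d <- dosage(gm)
  M <- nrow(d)
  keep <- rep(TRUE, M)
  starts <- unique(c(seq(1L, max(1L, M - 1L), by = step)))
  for (s in starts) {
    e <- min(M, s + windowSize - 1L)
    idx <- s:e
    idx <- idx[keep[idx]]
    if (length(idx) < 2) next
    r <- suppressWarnings(stats::cor(t(d[idx, , drop = FALSE]),
                                     use = "pairwise.complete.obs"))
    r2 <- r^2
    r2[!is.finite(r2)] <- 0  # constant or <2 complete obs: no evidence
    for (jj in 2:length(idx)) {
      if (!keep[idx[jj]]) next
      earlier <- idx[seq_len(jj - 1L)]
      earlier <- earlier[keep[earlier]]
      if (!length(earlier)) next
      pos <- match(earlier, idx)
      if (any(r2[pos, jj] > r2Threshold)) keep[idx[jj]] <- FALSE
    }
  }
  markerIds(gm)[keep]
}

#' Two-stage ancestry-informative-marker selection
#'
#' Stage 1 ranks all markers by global Fst across the continental groups
#' and takes the top `nGlobal`. Stage 2 then considers every unordered
#' pair of groups separately and, per pair, adds the `nPerPair` markers
#' of highest pairwise Fst not yet selected, sharpening resolution
#' between closely related groups. Ranking ties break by marker id; the
#' returned set is deduplicated and ordered by descending global Fst,
#' then marker id.
#'
#' @param fpContinental a [FrequencyPanel] of continental-mean
#'   frequencies (>= 2 populations, no missing values).
#' @param nGlobal number of stage-1 markers.
#' @param nPerPair number of stage-2 markers added per group pair.
#' @return list with `markers` (selected ids, deterministic order) and
#'   `fst`, a data.frame of per-marker global Fst plus one pairwise-Fst
#'   column per group pair (named `"A|B"`).
#' @export
selectAims <- function(fpContinental, nGlobal, nPerPair) {
  stopifnot(is(fpContinental, "FrequencyPanel"),
            nGlobal >= 1, nPerPair >= 0)
  f <- freq(fpContinental)
  if (nrow(f) < 2) stop("need at least two continental groups")
  if (anyNA(f)) stop("continental panel must be complete (run qcFilter first)")
  ids <- colnames(f)
  M <- length(ids)
  if (nGlobal > M) stop("nGlobal exceeds available markers")
  gl <- fstAcrossMarkers(f)
  fstTab <- data.frame(marker_id = ids, global_fst = unname(gl))
  ord <- order(-gl, ids)
  selected <- ids[ord[seq_len(nGlobal)]]
  pairs <- utils::combn(rownames(f), 2, simplify = FALSE)
  for (pr in pairs) {
    pw <- fstAcrossMarkers(f[pr, , drop = FALSE])
    fstTab[[paste(pr, collapse = "|")]] <- unname(pw)
    if (nPerPair == 0) next
    pord <- order(-pw, ids)
    cand <- setdiff(ids[pord], selected)
    if (length(cand) < nPerPair)
      stop("requested counts exceed available markers for pair ",
           paste(pr, collapse = "|"))
    selected <- c(selected, cand[seq_len(nPerPair)])
  }
  final <- selected[order(-gl[match(selected, ids)], selected)]
  list(markers = final, fst = fstTab)
}
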