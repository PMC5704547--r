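#' Read a genotype matrix from VCF or dosage TSV
#'
#' For VCF input the counted allele ("allele 1") is the ALT allele and
#' dosages are derived from the GT field (phased or unphased); `./.` and
#' half-calls become missing. Only biallelic SNP records are supported;
#' multiallelic records are skipped with a warning or rejected, per
#' `multiallelic`.
#'
#' The TSV layout is: a header row of sample ids, then one row per marker
#' with columns `marker_id`, `allele1`, optionally `allele2`, followed by
#' the per-sample dosages (0/1/2, `NA` or empty for no-call).
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param multiallelic `"skip"` (drop with a warning) or `"error"`.
#' @return a [GenotypeMatrix].
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "tsv"),
                          multiallelic = c("skip", "error")) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (format == "vcf") readGenotypesVcf(path, multiallelic) else readGenotypesTsv(path)
}

readGenotypesVcf <- function(path, multiallelic) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    if (multiallelic == "error")
      stop("multiallelic record(s) at: ",
           paste(utils::head(fix[multi, "ID"], 5), collapse = ", "))
    warning(sum(multi), " multiallelic record(s) skipped")
  }
  keep <- !multi
  ids <- unname(fix[keep, "ID"])
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[keep, "CHROM"][noid], ":", fix[keep, "POS"][noid])
  if (anyDuplicated(ids)) stop("duplicate marker id(s) in VCF: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  # count ALT copies; any missing or half-called genotype -> NA
  core <- sub(":.*", "", gt)
  d <- matrix(NA_integer_, nrow(core), ncol(core))
  a <- sub("[/|].*", "", core)
  b <- sub(".*[/|]", "", core)
  ok <- a %in% c("0", "1") & b %in% c("0", "1")
  d[ok] <- as.integer(a[ok]) + as.integer(b[ok])
  dimnames(d) <- list(ids, colnames(gt))
  GenotypeMatrix(d, allele1 = unname(alt[keep]),
                 allele2 = unname(fix[keep, "REF"]))
}

readGenotypesTsv <- function(path) {
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      colClasses = "character", na.strings = c("NA", "")),
    error = function(e) stop("malformed genotype TSV '", path, "': ",
                             conditionMessage(e)))
  need <- c("marker_id", "allele1")
  if (!all(need %in% names(tab)))
    stop("genotype TSV must have columns marker_id and allele1")
  if (anyDuplicated(tab$marker_id))
    stop("duplicate marker id(s): ",
         paste(unique(tab$marker_id[duplicated(tab$marker_id)]), collapse = ", "))
  meta <- intersect(c("marker_id", "allele1", "allele2"), names(tab))
  scols <- setdiff(names(tab), meta)
  if (!length(scols)) stop("genotype TSV contains no sample columns")
  d <- suppressWarnings(vapply(tab[scols], as.integer, integer(nrow(tab))))
  d <- matrix(as.integer(d), nrow = nrow(tab),
              dimnames = list(tab$marker_id, scols))
  bad <- !is.na(d) & !(d %in% VALID_DOSAGES)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid dosage at marker '%s', sample '%s' (line %d)",
                 rownames(d)[w[1]], colnames(d)[w[2]], w[1] + 1L))
  }
  GenotypeMatrix(d, allele1 = tab$allele1,
                 allele2 = if ("allele2" %in% names(tab)) tab$allele2 else NULL)
}

#' Write a genotype matrix as dosage TSV
#'
#' Inverse of [readGenotypes()] for the TSV layout; a write-then-read
#' round trip reproduces the object exactly.
#'
#' @param gm a [GenotypeMatrix].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(gm, path) {
  stopifnot(is(gm, "GenotypeMatrix"))
  tab <- data.frame(marker_id = markerIds(gm),
                    allele1 = unname(allele1(gm)),
                    allele2 = unname(allele2(gm)),
                    dosage(gm), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a population allele-frequency panel from TSV
#'
#' Layout: columns `marker_id`, `allele1`, then one frequency column per
#' reference population. An optional second header line starting with
#' `#group` assigns each population to a continental group; otherwise
#' groups can be set later (see [continentalFrequencies()]).
#'
#' @param path input file.
#' @param continentalGroups optional named character vector mapping
#'   population id to continental group, overriding any `#group` line.
#' @return a [FrequencyPanel] (populations x markers).
#' @export
readFrequencyPanel <- function(path, continentalGroups = NULL) {
  if (!file.exists(path)) stop("frequency panel not found: ", path)
  first <- readLines(path, n = 2)
  grpline <- length(first) > 1 && startsWith(first[2], "#group")
  hdr <- strsplit(first[1], "\t", fixed = TRUE)[[1]]
  tab <- utils::read.table(path, header = FALSE, sep = "\t", skip = if (grpline) 2 else 1,
                           col.names = hdr, check.names = FALSE,
                           colClasses = "character", na.strings = c("NA", ""))
  names(tab) <- hdr
  if (!all(c("marker_id", "allele1") %in% hdr))
    stop("frequency panel must have columns marker_id and allele1")
  if (anyDuplicated(tab$marker_id))
    stop("duplicate marker id(s) in panel")
  pops <- setdiff(hdr, c("marker_id", "allele1"))
  f <- t(vapply(tab[pops], as.numeric, numeric(nrow(tab))))
  if (nrow(tab) == 1L) f <- matrix(f, ncol = 1L, dimnames = list(pops, NULL))
  dimnames(f) <- list(pops, tab$marker_id)
  grp <- rep(NA_character_, length(pops))
  names(grp) <- pops
  if (grpline) {
    gl <- strsplit(first[2], "\t", fixed = TRUE)[[1]][-(1:2)]
    grp[] <- gl[seq_along(pops)]
  }
  if (!is.null(continentalGroups)) grp[names(continentalGroups)] <- continentalGroups
  FrequencyPanel(f, allele1 = tab$allele1, continentalGroup = unname(grp))
}

#' Write a frequency panel as TSV
#'
#' Inverse of [readFrequencyPanel()]; continental group labels, when
#' present, are stored on a `#group` line under the header.
#'
#' @param fp a [FrequencyPanel].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFrequencyPanel <- function(fp, path) {
  stopifnot(is(fp, "FrequencyPanel"))
  pops <- populationIds(fp)
  hdr <- c("marker_id", "allele1", pops)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = "\t"), con)
  grp <- unname(continentalGroup(fp))
  if (!all(is.na(grp)))
    writeLines(paste(c("#group", "", grp), collapse = "\t"), con)
  tab <- data.frame(marker_id = markerIds(fp),
                    allele1 = unname(allele1(fp)),
                    t(freq(fp)), check.names = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read sample metadata (self-reported ethnicities and carrier flags)
#'
#' CSV layout: `sample_id`, `form_ethnicities` (semicolon-joined labels
#' from the requisition form), `consult_ethnicities` (semicolon-joined;
#' empty cell = no consult record), then one column per disease with
#' values `carrier`, `non-carrier` or `untested`.
#'
#' Free-text labels are passed through [mapEthnicityLabels()]; a sample
#' whose form contains bare "Other" with no write-in clarification is
#' flagged `excluded` and dropped by downstream concordance analysis.
#'
#' @param path CSV file.
#' @param synonyms synonym table for [mapEthnicityLabels()].
#' @return a data.frame with list-columns `form` and `consult` (character
#'   vectors of controlled labels; `consult` is `NULL` where no consult
#'   happened), logical columns `has_consult` and `excluded`, and one
#'   factor column per disease. The disease column names are recorded in
#'   the `diseases` attribute.
#' @export
readSampleMetadata <- function(path, synonyms = ethnicitySynonyms()) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = character())
  need <- c("sample_id", "form_ethnicities", "consult_ethnicities")
  if (!all(need %in% names(tab)))
    stop("metadata CSV must have columns ", paste(need, collapse = ", "))
  diseases <- setdiff(names(tab), need)
  split_labels <- function(s) {
    v <- strsplit(s, ";", fixed = TRUE)[[1]]
    trimws(v[nzchar(trimws(v))])
  }
  n <- nrow(tab)
  form <- vector("list", n); consult <- vector("list", n)
  excluded <- logical(n); has_consult <- logical(n)
  for (i in seq_len(n)) {
    fr <- mapEthnicityLabels(split_labels(tab$form_ethnicities[i]), synonyms)
    excluded[i] <- anyNA(fr)
    form[[i]] <- fr[!is.na(fr)]
    cs <- split_labels(tab$consult_ethnicities[i])
    has_consult[i] <- length(cs) > 0
    if (has_consult[i]) {
      cl <- mapEthnicityLabels(cs, synonyms)
      consult[[i]] <- cl[!is.na(cl)]
    }
  }
  out <- data.frame(sample_id = tab$sample_id, stringsAsFactors = FALSE)
  out$form <- form
  out$consult <- consult
  out$has_consult <- has_consult
  out$excluded <- excluded
  for (d in diseases) {
    v <- tab[[d]]
    bad <- !(v %in% c("carrier", "non-carrier", "untested"))
    if (any(bad)) stop("disease column '", d, "' has invalid value(s): ",
                       paste(unique(v[bad]), collapse = ", "))
    out[[d]] <- factor(v, levels = c("carrier", "non-carrier", "untested"))
  }
  attr(out, "diseases") <- diseases
  out
}
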