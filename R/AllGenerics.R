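#' @rdname GenotypeMatrix-class
#' @param x a `GenotypeMatrix`, `FrequencyPanel` or `AncestryEstimate`.
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("allele1", function(x) standardGeneric("allele1"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("allele2", function(x) standardGeneric("allele2"))

#' @rdname FrequencyPanel-class
#' @param x object.
#' @export
setGeneric("populationIds", function(x) standardGeneric("populationIds"))

#' @rdname FrequencyPanel-class
#' @export
setGeneric("freq", function(x) standardGeneric("freq"))

#' @rdname FrequencyPanel-class
#' @export
setGeneric("continentalGroup", function(x) standardGeneric("continentalGroup"))

#' @rdname AncestryEstimate-class
#' @param x object.
#' @export
setGeneric("ancestryProportions", function(x) standardGeneric("ancestryProportions"))

#' Label of the largest ancestry component
#'
#' Returns, per sample, the population label carrying the largest estimated
#' ancestry proportion. Exact ties are broken in favour of the first
#' (left-most) population and flagged in the `tied` attribute.
#'
#' @param x an [AncestryEstimate] or a numeric ancestry vector.
#' @param ... unused.
#' @return character vector of population labels (NA where no estimate was
#'   possible), with a logical attribute `tied`.
#' @export
setGeneric("maxAncestralGroup", function(x, ...) standardGeneric("maxAncestralGroup"))
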