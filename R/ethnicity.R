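#' Controlled self-reported ethnicity vocabulary
#'
#' The 12-option check-all-that-apply list used on clinical requisition
#' forms: 11 substantive labels plus "Other" (which requires a write-in
#' clarification to be usable).
#'
#' @return character vector of the 12 controlled labels.
#' @export
ethnicityVocabulary <- function() {
  c("African", "Central Asian", "East Asian", "European", "Jewish",
    "Latin American", "Mediterranean", "Middle Eastern", "Native American",
    "South Asian", "South East Asian", "Other")
}

#' Default free-text synonym table for ethnicity labels
#'
#' Maps common write-ins to the controlled vocabulary, e.g. Caucasian or
#' White to European. Extend or replace to match local intake forms.
#'
#' @return named character vector: names are lower-cased raw strings,
#'   values are controlled labels.
#' @export
ethnicitySynonyms <- function() {
  c("caucasian"        = "European",
    "white"            = "European",
    "caucasian/white"  = "European",
    "black"            = "African",
    "african american" = "African",
    "afro-american"    = "African",
    "ashkenazi"        = "Jewish",
    "ashkenazi jewish" = "Jewish",
    "sephardic"        = "Jewish",
    "hispanic"         = "Latin American",
    "latino"           = "Latin American",
    "latina"           = "Latin American",
    "hispanic/latino"  = "Latin American",
    "asian"            = "East Asian",
    "chinese"          = "East Asian",
    "japanese"         = "East Asian",
    "korean"           = "East Asian",
    "indian"           = "South Asian",
    "pakistani"        = "South Asian",
    "filipino"         = "South East Asian",
    "vietnamese"       = "South East Asian",
    "thai"             = "South East Asian",
    "italian"          = "Mediterranean",
    "greek"            = "Mediterranean",
    "american indian"  = "Native American",
    "arab"             = "Middle Eastern",
    "persian"          = "Middle Eastern")
}

#' Map raw self-reported ethnicity strings to the controlled vocabulary
#'
#' Controlled labels pass through unchanged (case-insensitively). Other
#' strings are looked up in the synonym table. A bare "Other" with no
#' write-in clarification cannot be analysed and maps to `NA` (the
#' excluded flag). Unmapped write-ins are kept verbatim with a warning so
#' the synonym table can be extended.
#'
#' @param raw character vector of raw labels.
#' @param synonyms named character vector (see [ethnicitySynonyms()]).
#' @return character vector of the same length; `NA` marks excluded
#'   entries.
#' @examples
#' mapEthnicityLabels(c("Caucasian", "European", "Other"))
#' @export
mapEthnicityLabels <- function(raw, synonyms = ethnicitySynonyms()) {
  vocab <- ethnicityVocabulary()
  out <- character(length(raw))
  key <- tolower(trimws(raw))
  canon <- stats::setNames(vocab, tolower(vocab))
  for (i in seq_along(raw)) {
    if (key[i] == "other" || key[i] == "") {
      out[i] <- NA_character_
    } else if (key[i] %in% names(canon)) {
      out[i] <- canon[[key[i]]]
    } else if (key[i] %in% names(synonyms)) {
      out[i] <- synonyms[[key[i]]]
    } else {
      warning("unmapped ethnicity write-in kept verbatim: '", raw[i], "'")
      out[i] <- raw[i]
    }
  }
  out
}
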