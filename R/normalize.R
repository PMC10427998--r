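#' Normalize a taxon name for matching
#'
#' Cleans raw taxon labels so that names coming from different classifier
#' pipelines can be compared against the curated reference list. The rules
#' are: trim leading/trailing whitespace; collapse internal runs of
#' whitespace and underscores to a single space; and drop a trailing
#' "sp.", "sp" or "spp." token (case-insensitive) since the reference list
#' records genus-level entries without it. The original letter case of the
#' name is preserved; use [taxon_key()] for the case-folded comparison key.
#'
#' The function is idempotent: `normalize_taxon_name(normalize_taxon_name(x))`
#' is identical to `normalize_taxon_name(x)`.
#'
#' @param x Character vector of raw taxon names.
#' @return Character vector of the same length. Whitespace-only input (or a
#'   bare "sp."-type token) normalizes to the empty string; callers decide
#'   whether that is an error.
#' @examples
#' normalize_taxon_name("Vibrio sp.")              # "Vibrio"
#' normalize_taxon_name("  Pseudomonas_aeruginosa ") # "Pseudomonas aeruginosa"
#' normalize_taxon_name("Desulfobacter")           # unchanged
#' @export
normalize_taxon_name <- function(x) {
  stopifnot(is.character(x) || all(is.na(x)))
  x <- as.character(x)
  out <- stringr::str_replace_all(x, "[\\s_]+", " ")
  out <- stringr::str_trim(out)
  # drop trailing sp./sp/spp. tokens; the + makes repeated suffixes collapse
  # in one pass, which is what guarantees idempotence
  out <- stringr::str_replace(out, stringr::regex("( spp?\\.?)+$", ignore_case = TRUE), "")
  out[stringr::str_detect(out, stringr::regex("^spp?\\.?$", ignore_case = TRUE))] <- ""
  out[is.na(x)] <- NA_character_
  out
}

#' Case-folded comparison key for a taxon name
#'
#' @param x Character vector of taxon names (raw or normalized).
#' @return Lower-cased normalized names, used as keys of the reference
#'   lookup map.
#' @export
taxon_key <- function(x) {
  tolower(normalize_taxon_name(x))
}
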