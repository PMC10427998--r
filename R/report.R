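REPORT_COLUMNS <- c(
  "station", "total_reads", "n_taxa", "shannon_h_bits",
  "pct_egi", "pct_egiii", "pct_not_assigned", "pct_not_in_list",
  "f_egi", "f_egiii", "index_value", "index_display", "status", "flags"
)

#' Write a station assessment report
#'
#' Writes one record per station with every assessment field, in input
#' station order. Numeric fields are written at full precision; the index
#' additionally gets a 2-decimal display column (`index_display`). TSV
#' reports start with `#`-prefixed header lines echoing the effective
#' weights, boundaries and denominator policy, so every report carries its
#' own provenance; the JSON format nests the same configuration under
#' `"config"`.
#'
#' @param assessment A `microgambi_assessment` from [assess_all()].
#' @param file Output path.
#' @param format `"tsv"` (default) or `"json"`.
#' @return `file`, invisibly.
#' @export
write_report <- function(assessment, file, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(assessment, "microgambi_assessment"))
  if (nrow(assessment) == 0) rlang::abort("assessment has no stations to report")
  cfg <- assessment_config(assessment)

  flat <- tidy(assessment)
  flat$index_display <- round(flat$index_value, 2)
  flat$status <- as.character(flat$status)
  flat <- flat[, REPORT_COLUMNS]

  if (format == "tsv") {
    hdr <- c(
      sprintf("# microgambi report"),
      sprintf("# weight_egi=%.15g weight_egiii=%.15g", cfg$weight_egi, cfg$weight_egiii),
      sprintf("# class_boundaries=%s",
              paste(sprintf("%.15g", cfg$class_boundaries), collapse = ",")),
      sprintf("# denominator_policy=%s", cfg$denominator_policy),
      sprintf("# unmatched_warn_threshold=%.15g", cfg$unmatched_warn_threshold)
    )
    writeLines(hdr, file)
    # readr writes doubles in shortest round-trip form, i.e. full precision
    readr::write_tsv(flat, file, append = TRUE, col_names = TRUE, na = "NA")
  } else {
    jsonlite::write_json(
      list(
        config = list(
          weight_egi = cfg$weight_egi, weight_egiii = cfg$weight_egiii,
          class_boundaries = cfg$class_boundaries,
          denominator_policy = cfg$denominator_policy,
          unmatched_warn_threshold = cfg$unmatched_warn_threshold
        ),
        stations = flat
      ),
      file, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
    )
  }
  invisible(file)
}

#' Read back a TSV assessment report
#'
#' Parses a report written by [write_report()] (TSV format), skipping the
#' provenance header lines.
#'
#' @param file Path to the report.
#' @return Tibble with the report columns; `status` restored as a factor.
#' @export
read_report <- function(file) {
  out <- readr::read_tsv(file, comment = "#", na = "NA",
                         col_types = readr::cols(
                           station = readr::col_character(),
                           status = readr::col_character(),
                           flags = readr::col_character(),
                           .default = readr::col_double()
                         ),
                         progress = FALSE)
  out$total_reads <- as.integer(out$total_reads)
  out$n_taxa <- as.integer(out$n_taxa)
  out$status <- factor(out$status, levels = STATUS_LEVELS)
  out$flags[is.na(out$flags)] <- ""
  out
}
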