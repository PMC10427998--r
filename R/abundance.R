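#' Read a taxa-by-station read-count table
#'
#' Reads a delimited text table of non-negative integer read counts with
#' taxa in rows and sampling stations in columns: the first column holds
#' taxon names, the header row station identifiers. The delimiter is taken
#' from `delim`, or sniffed from the first line (tab when one is present,
#' comma otherwise). Stations whose layout is the other way around can be
#' read with `transpose = TRUE`; orientation is never auto-detected, since
#' auto-detection misfires on square tables.
#'
#' Counts must be integers: fractional or negative cells are rejected with
#' the offending taxon and station named, because the downstream
#' computations sum reads — relative abundances as input would corrupt
#' richness and diversity. Empty cells are read as zero. Rows whose counts
#' are all zero are retained (they affect nothing downstream). Rows that
#' duplicate a taxon after name normalization (e.g. "Vibrio" and
#' "Vibrio sp.") are merged by summation with a warning, or rejected when
#' `strict = TRUE`.
#'
#' @param file Path to a TSV/CSV file, or a character vector of lines.
#' @param delim Field delimiter; `NULL` (default) sniffs tab vs comma.
#' @param transpose Logical; set `TRUE` when stations are rows in the file.
#' @param strict Logical; treat duplicate taxon rows as an error.
#' @return An abundance tibble: column `taxon` (character) followed by one
#'   integer column per station, in file order.
#' @export
read_abundance_table <- function(file, delim = NULL, transpose = FALSE,
                                 strict = FALSE) {
  if (length(file) == 1 && !grepl("[\t\n,]", file)) {
    if (!file.exists(file)) {
      rlang::abort(sprintf("abundance table not found: '%s'", file))
    }
    lines <- readr::read_lines(file)
  } else {
    lines <- unlist(strsplit(file, "\n", fixed = TRUE))
  }
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 1) rlang::abort("abundance table is empty")
  if (is.null(delim)) delim <- if (grepl("\t", lines[[1]])) "\t" else ","

  raw <- readr::read_delim(
    I(paste0(paste(lines, collapse = "\n"), "\n")),
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    name_repair = "minimal", progress = FALSE
  )
  if (ncol(raw) < 2) {
    rlang::abort("abundance table needs a taxon column plus at least one station column")
  }

  if (transpose) {
    station_ids <- as.character(raw[[1]])
    taxa <- names(raw)[-1]
    mat <- t(as.matrix(raw[, -1, drop = FALSE]))
    raw <- tibble::as_tibble(
      cbind(data.frame(taxon = taxa, stringsAsFactors = FALSE),
            as.data.frame(mat, stringsAsFactors = FALSE)),
      .name_repair = "minimal"
    )
    names(raw) <- c("taxon", station_ids)
  }

  station_ids <- names(raw)[-1]
  if (anyDuplicated(station_ids)) {
    rlang::abort(sprintf(
      "duplicate station id(s): %s",
      paste(unique(station_ids[duplicated(station_ids)]), collapse = ", ")
    ))
  }

  taxa <- as.character(raw[[1]])
  counts <- as.data.frame(raw[, -1, drop = FALSE])
  for (j in seq_along(counts)) {
    cell <- stringr::str_trim(as.character(counts[[j]]))
    cell[is.na(cell) | cell == ""] <- "0"
    bad <- !grepl("^[0-9]+$", cell)
    if (any(bad)) {
      i <- which(bad)[1]
      rlang::abort(sprintf(
        "non-integer count '%s' at taxon '%s', station '%s' (counts must be non-negative integers)",
        cell[i], taxa[i], station_ids[j]
      ))
    }
    counts[[j]] <- as.integer(cell)
  }

  out <- tibble::as_tibble(
    cbind(data.frame(taxon = taxa, stringsAsFactors = FALSE), counts),
    .name_repair = "minimal"
  )
  names(out) <- c("taxon", station_ids)
  merge_duplicate_taxa(out, strict = strict)
}

merge_duplicate_taxa <- function(tbl, strict = FALSE) {
  keys <- taxon_key(tbl$taxon)
  if (!anyDuplicated(keys)) return(tbl)
  dups <- unique(tbl$taxon[duplicated(keys)])
  if (strict) {
    rlang::abort(sprintf("duplicate taxon row(s) after normalization: %s",
                         paste(dups, collapse = ", ")))
  }
  rlang::warn(sprintf(
    "%d taxon row(s) duplicated after normalization were merged by summation: %s",
    length(dups), paste(utils::head(dups, 5), collapse = ", ")
  ))
  first <- match(unique(keys), keys)
  merged <- rowsum(as.matrix(tbl[, -1, drop = FALSE]), group = keys,
                   reorder = FALSE)
  out <- tibble::as_tibble(
    cbind(data.frame(taxon = tbl$taxon[first], stringsAsFactors = FALSE),
          as.data.frame(merged)),
    .name_repair = "minimal"
  )
  names(out) <- names(tbl)
  tibble::remove_rownames(out)
}

#' Read an abundance table from a BIOM file
#'
#' Optional reader for the BIOM exchange format, returning the same
#' taxa-by-station tibble contract as [read_abundance_table()]. Requires
#' the `biomformat` package.
#'
#' @param file Path to a BIOM (JSON) file.
#' @inheritParams read_abundance_table
#' @return An abundance tibble (column `taxon`, then station columns).
#' @export
read_abundance_biom <- function(file, strict = FALSE) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    rlang::abort("reading BIOM files requires the 'biomformat' package")
  }
  b <- biomformat::read_biom(file)
  m <- as.matrix(biomformat::biom_data(b))
  if (any(m < 0) || any(m != round(m))) {
    rlang::abort("BIOM matrix contains negative or fractional values; counts required")
  }
  out <- tibble::as_tibble(
    cbind(data.frame(taxon = rownames(m), stringsAsFactors = FALSE),
          as.data.frame(m)),
    .name_repair = "minimal"
  )
  names(out) <- c("taxon", colnames(m))
  out[-1] <- lapply(out[-1], as.integer)
  merge_duplicate_taxa(out, strict = strict)
}

#' Validate an abundance tibble
#'
#' Checks the container contract: a `taxon` character column first, at
#' least one station column, all counts non-negative integers, station ids
#' unique, taxon names unique after normalization.
#'
#' @param tbl An abundance tibble.
#' @return `tbl`, invisibly, or an error describing the violation.
#' @export
validate_abundance <- function(tbl) {
  if (!is.data.frame(tbl) || ncol(tbl) < 2 || names(tbl)[1] != "taxon") {
    rlang::abort("abundance table must have a 'taxon' column followed by station columns")
  }
  if (anyDuplicated(names(tbl)[-1])) rlang::abort("duplicate station ids")
  if (anyDuplicated(taxon_key(tbl$taxon))) {
    rlang::abort("duplicate taxon names after normalization")
  }
  vals <- as.matrix(tbl[, -1, drop = FALSE])
  if (!is.numeric(vals) || any(is.na(vals)) || any(vals < 0) ||
      any(vals != round(vals))) {
    rlang::abort("counts must be non-negative integers with no missing values")
  }
  invisible(tbl)
}

#' Station identifiers of an abundance tibble
#' @param tbl An abundance tibble.
#' @return Character vector of station ids in table order.
#' @export
station_ids <- function(tbl) {
  names(tbl)[-1]
}

#' Write an abundance tibble as TSV
#' @param tbl An abundance tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_abundance_table <- function(tbl, file) {
  readr::write_tsv(tbl, file)
  invisible(file)
}
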