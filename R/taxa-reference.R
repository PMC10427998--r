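#' @keywords internal
EG_LEVELS <- c("EGI", "EGIII", "not assigned")

#' Default dialect table mapping raw EG codes to canonical labels
#'
#' Spreadsheet variants of the reference list encode the ecological group
#' as "I"/"III", "EG I"/"EG III", "EGI"/"EGIII", and mark uncategorized
#' taxa as "not assigned", "NA" or a blank cell. Matching is
#' case-insensitive after trimming and underscore/whitespace collapsing.
#'
#' @return Named character vector: names are the accepted raw tokens
#'   (lower case), values the canonical labels `"EGI"`, `"EGIII"`,
#'   `"not assigned"`.
#' @export
default_eg_dialect <- function() {
  stats::setNames(
    c("EGI", "EGI", "EGI", "EGIII", "EGIII", "EGIII",
      "not assigned", "not assigned", "not assigned"),
    c("i", "eg i", "egi", "iii", "eg iii", "egiii",
      "not assigned", "na", "") # blank cell means "not assigned"
  )
}

canonical_eg <- function(raw, dialect = default_eg_dialect()) {
  key <- tolower(stringr::str_trim(stringr::str_replace_all(
    ifelse(is.na(raw), "", raw), "[\\s_]+", " "
  )))
  # match() rather than dialect[key]: a blank cell must hit the "" entry,
  # and name-indexing a vector by "" always returns NA
  unname(dialect[match(key, names(dialect))]) # NA for unrecognized tokens
}

new_issue <- function(row_number, severity, code, message) {
  tibble::tibble(
    row_number = as.integer(row_number),
    severity = severity, code = code, message = message
  )
}

empty_issues <- function() {
  tibble::tibble(
    row_number = integer(), severity = character(),
    code = character(), message = character()
  )
}

#' Read and validate a taxa reference list
#'
#' Parses the tab-separated curated reference list that assigns microbial
#' taxa to ecological groups. The expected column order is: row number,
#' taxon name, NCBI accession, WoRMS accession, ecological group, evidence
#' links (DOI/URI), literature, comments. Files carrying only the first
#' five columns are accepted; the trailing evidence columns are carried
#' verbatim and never interpreted.
#'
#' Structural problems are collected as validation issues rather than
#' thrown one at a time: rows with too few columns (`BAD_COLUMN_COUNT`),
#' empty names after normalization (`EMPTY_NAME`), unrecognized ecological
#' group codes (`INVALID_EG_CODE`), duplicated normalized names with the
#' same group (`DUPLICATE_NAME`, warning; the first record wins) and with
#' conflicting groups (`CONFLICTING_EG`, error; the index would be
#' ambiguous). Rows with error-severity issues are excluded from the
#' usable records. With `strict = TRUE` any error-severity issue aborts.
#'
#' @param file Path to a TSV file, or a character vector of lines.
#' @param header Logical; is the first row a header? Default `TRUE`.
#' @param strict Logical; abort on any error-severity issue. Default `FALSE`.
#' @param eg_dialect Named character vector mapping raw EG tokens to
#'   canonical labels; see [default_eg_dialect()].
#' @param version_label Optional label recorded on the result (defaults to
#'   the file name).
#' @return A `taxa_reference`: a tibble with columns `row_number`, `name`,
#'   `name_key`, `ncbi_accession`, `worms_accession`, `eg` (factor with
#'   levels EGI, EGIII, not assigned), `evidence_links`, `literature`,
#'   `comments`, plus attributes `issues` (see [taxa_issues()]) and
#'   `version_label`.
#' @export
read_taxa_reference <- function(file, header = TRUE, strict = FALSE,
                                eg_dialect = default_eg_dialect(),
                                version_label = NULL) {
  if (length(file) == 1 && !grepl("[\t\n]", file)) {
    if (!file.exists(file)) {
      rlang::abort(sprintf("taxa reference file not found: '%s'", file))
    }
    lines <- readr::read_lines(file)
    if (is.null(version_label)) version_label <- basename(file)
  } else {
    lines <- unlist(strsplit(file, "\n", fixed = TRUE))
    if (is.null(version_label)) version_label <- "<inline>"
  }
  if (header && length(lines) >= 1) lines <- lines[-1]
  lines <- lines[!grepl("^\\s*$", lines)]

  issues <- empty_issues()
  n <- length(lines)
  if (n == 0) {
    return(new_taxa_reference(empty_reference_records(), issues, version_label))
  }

  # count columns from tabs, not split length: strsplit drops trailing
  # empty fields, and a blank trailing EG cell is still a real column
  ncol_row <- stringr::str_count(lines, stringr::fixed("\t")) + 1L
  cells <- Map(function(r, n) c(r, rep("", n - length(r))),
               strsplit(lines, "\t", fixed = TRUE), ncol_row)
  get_col <- function(i) {
    vapply(cells, function(r) if (length(r) >= i) r[[i]] else NA_character_,
           character(1))
  }

  rec <- tibble::tibble(
    row_number = seq_len(n),
    name_raw = get_col(2),
    ncbi_accession = get_col(3),
    worms_accession = get_col(4),
    eg_raw = get_col(5),
    evidence_links = get_col(6),
    literature = get_col(7),
    comments = get_col(8)
  )
  # prefer the file's own row numbers (column A) when they parse
  file_rownum <- suppressWarnings(as.integer(get_col(1)))
  rec$row_number <- ifelse(is.na(file_rownum), rec$row_number, file_rownum)

  bad <- ncol_row < 5
  if (any(bad)) {
    issues <- dplyr::bind_rows(issues, new_issue(
      rec$row_number[bad], "error", "BAD_COLUMN_COUNT",
      sprintf("row has %d column(s); at least 5 (through the EG column) required",
              ncol_row[bad])
    ))
  }

  rec$name <- normalize_taxon_name(ifelse(is.na(rec$name_raw), "", rec$name_raw))
  rec$name_key <- tolower(rec$name)
  empty_name <- !bad & rec$name == ""
  if (any(empty_name)) {
    issues <- dplyr::bind_rows(issues, new_issue(
      rec$row_number[empty_name], "error", "EMPTY_NAME",
      "taxon name is empty after normalization"
    ))
  }

  rec$eg <- canonical_eg(rec$eg_raw, eg_dialect)
  bad_eg <- !bad & !empty_name & is.na(rec$eg)
  if (any(bad_eg)) {
    issues <- dplyr::bind_rows(issues, new_issue(
      rec$row_number[bad_eg], "error", "INVALID_EG_CODE",
      sprintf("unrecognized ecological group code '%s'", rec$eg_raw[bad_eg])
    ))
  }

  keep <- !bad & !empty_name & !bad_eg
  rec <- rec[keep, , drop = FALSE]

  # duplicate handling on normalized keys: first record wins; identical EG
  # is a warning, conflicting EG an error (the dropped record is the later one)
  if (nrow(rec) > 0) {
    first_idx <- match(rec$name_key, rec$name_key)
    dup <- first_idx != seq_len(nrow(rec))
    if (any(dup)) {
      same_eg <- rec$eg[dup] == rec$eg[first_idx[dup]]
      if (any(same_eg)) {
        issues <- dplyr::bind_rows(issues, new_issue(
          rec$row_number[dup][same_eg], "warning", "DUPLICATE_NAME",
          sprintf("duplicate of '%s' (row %d) with the same EG; first record kept",
                  rec$name[first_idx[dup]][same_eg],
                  rec$row_number[first_idx[dup]][same_eg])
        ))
      }
      if (any(!same_eg)) {
        issues <- dplyr::bind_rows(issues, new_issue(
          rec$row_number[dup][!same_eg], "error", "CONFLICTING_EG",
          sprintf("duplicate of '%s' (row %d) with a conflicting EG (%s vs %s)",
                  rec$name[first_idx[dup]][!same_eg],
                  rec$row_number[first_idx[dup]][!same_eg],
                  rec$eg[dup][!same_eg], rec$eg[first_idx[dup]][!same_eg])
        ))
      }
      rec <- rec[!dup, , drop = FALSE]
    }
  }

  if (strict && any(issues$severity == "error")) {
    rlang::abort(c(
      sprintf("taxa reference '%s' has %d error-severity validation issue(s)",
              version_label, sum(issues$severity == "error")),
      utils::head(issues$message[issues$severity == "error"], 5)
    ))
  }

  rec$eg <- factor(rec$eg, levels = EG_LEVELS)
  rec <- dplyr::select(rec, "row_number", "name", "name_key",
                       "ncbi_accession", "worms_accession", "eg",
                       "evidence_links", "literature", "comments")
  new_taxa_reference(rec, issues, version_label)
}

empty_reference_records <- function() {
  tibble::tibble(
    row_number = integer(), name = character(), name_key = character(),
    ncbi_accession = character(), worms_accession = character(),
    eg = factor(character(), levels = EG_LEVELS),
    evidence_links = character(), literature = character(),
    comments = character()
  )
}

new_taxa_reference <- function(records, issues, version_label) {
  structure(
    records,
    issues = issues,
    version_label = version_label,
    class = c("taxa_reference", class(tibble::tibble()))
  )
}

#' Validation issues collected while parsing a taxa reference
#'
#' @param ref A `taxa_reference` from [read_taxa_reference()].
#' @return Tibble with columns `row_number`, `severity` ("warning" or
#'   "error"), `code`, `message`.
#' @export
taxa_issues <- function(ref) {
  stopifnot(inherits(ref, "taxa_reference"))
  attr(ref, "issues")
}

#' Write a validation report for a taxa reference
#'
#' @param ref A `taxa_reference`.
#' @param file Output path for the tab-separated issue report.
#' @return The issues tibble, invisibly.
#' @export
write_validation_report <- function(ref, file) {
  issues <- taxa_issues(ref)
  readr::write_tsv(issues, file)
  invisible(issues)
}

#' Match query taxon names against a reference
#'
#' Exact matching is on the case-folded normalized name. When
#' `genus_fallback = TRUE` and a query has no exact hit, the first
#' whitespace-delimited token of the normalized query (its genus) is tried
#' as a second pass. Queries absent from the list map to the category
#' `"not in list"` — a valid outcome, not an error, and distinct from
#' `"not assigned"` (present in the list but of unknown ecological
#' function).
#'
#' @param ref A `taxa_reference`.
#' @param query Character vector of taxon names (raw; normalized internally).
#' @param genus_fallback Logical; retry unmatched queries at genus level.
#'   Default `FALSE`.
#' @return Tibble with one row per query: `query`, `category` (factor:
#'   EGI, EGIII, not assigned, not in list), `matched_name`, `match_level`
#'   (exact, genus_fallback, none).
#' @export
lookup_taxon <- function(ref, query, genus_fallback = FALSE) {
  stopifnot(inherits(ref, "taxa_reference"))
  keys <- taxon_key(query)
  idx <- match(keys, ref$name_key)
  level <- ifelse(is.na(idx), "none", "exact")
  if (genus_fallback && any(is.na(idx))) {
    miss <- which(is.na(idx))
    genus <- stringr::word(keys[miss], 1)
    gidx <- match(genus, ref$name_key)
    hit <- !is.na(gidx)
    idx[miss[hit]] <- gidx[hit]
    level[miss[hit]] <- "genus_fallback"
  }
  category <- ifelse(is.na(idx), "not in list", as.character(ref$eg[idx]))
  tibble::tibble(
    query = as.character(query),
    category = factor(category, levels = c(EG_LEVELS, "not in list")),
    matched_name = ifelse(is.na(idx), NA_character_, ref$name[idx]),
    match_level = factor(level, levels = c("exact", "genus_fallback", "none"))
  )
}

#' Summarize a taxa reference by ecological group
#'
#' Counts records (taxa, not reads) in each ecological group. The four
#' components always satisfy `total = n_egi + n_egiii + n_not_assigned`.
#'
#' @param ref A `taxa_reference`.
#' @return One-row tibble: `total`, `n_egi`, `n_egiii`, `n_not_assigned`.
#' @export
summarize_reference <- function(ref) {
  stopifnot(inherits(ref, "taxa_reference"))
  tibble::tibble(
    total = nrow(ref),
    n_egi = sum(ref$eg == "EGI"),
    n_egiii = sum(ref$eg == "EGIII"),
    n_not_assigned = sum(ref$eg == "not assigned")
  )
}

#' Serialize a taxa reference back to the 8-column TSV layout
#'
#' @param ref A `taxa_reference`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_taxa_reference <- function(ref, file) {
  stopifnot(inherits(ref, "taxa_reference"))
  out <- tibble::tibble(
    A = ref$row_number, B = ref$name, C = ref$ncbi_accession,
    D = ref$worms_accession, E = as.character(ref$eg),
    F = ref$evidence_links, G = ref$literature, H = ref$comments
  )
  names(out) <- c("no", "taxon", "ncbi_accession", "worms_accession",
                  "EG", "links", "literature", "comments")
  readr::write_tsv(out, file, na = "")
  invisible(file)
}

#' @export
glance.taxa_reference <- function(x, ...) {
  s <- summarize_reference(x)
  issues <- taxa_issues(x)
  dplyr::mutate(s,
    n_issues = nrow(issues),
    n_errors = sum(issues$severity == "error"),
    version_label = attr(x, "version_label") %||% NA_character_
  )
}

#' @export
print.taxa_reference <- function(x, ...) {
  s <- summarize_reference(x)
  cat(sprintf(
    "<taxa_reference '%s'> %d taxa (%d EGI, %d EGIII, %d not assigned), %d issue(s)\n",
    attr(x, "version_label") %||% "?", s$total, s$n_egi, s$n_egiii,
    s$n_not_assigned, nrow(taxa_issues(x))
  ))
  NextMethod()
}
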