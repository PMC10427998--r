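STATUS_LEVELS <- c("high", "good", "moderate", "poor", "bad", "unclassifiable")

#' Configuration of the biotic index: weights, class boundaries, policies
#'
#' The index is a weighted mean of the relative read abundances of the two
#' ecological groups, `(weight_egi * f_egi + weight_egiii * f_egiii) / 100`,
#' so its range is `[weight_egi, weight_egiii]`. The four class boundaries
#' cut that range into the five ecological status classes (high, good,
#' moderate, poor, bad). Defaults follow the published convention of the
#' AMBI family of indices: weights 0 and 6, boundaries 1.2, 3.3, 4.3, 5.5.
#'
#' `denominator_policy` controls which reads the group fractions are taken
#' over: `"assigned_only"` (default) renormalizes over EGI + EGIII reads,
#' so `f_egi + f_egiii = 100` whenever any assigned reads exist;
#' `"all_reads"` divides by the station total, counting unassigned and
#' unlisted reads against both groups. Both sets of percentages are always
#' reported; the policy decides which feeds the index.
#'
#' @param weight_egi Non-negative coefficient of the sensitive group
#'   (default 0).
#' @param weight_egiii Coefficient of the tolerant group; must exceed
#'   `weight_egi` (default 6).
#' @param class_boundaries Strictly increasing numeric vector of length 4
#'   inside `[weight_egi, weight_egiii]` (default `c(1.2, 3.3, 4.3, 5.5)`).
#' @param denominator_policy `"assigned_only"` or `"all_reads"`.
#' @param unmatched_warn_threshold Percentage of reads not assigned plus
#'   not in the list above which a station is flagged for poor reference
#'   coverage (default 20).
#' @return A `microgambi_config` list.
#' @examples
#' cfg <- microgambi_config()
#' microgambi_index(40, 60, cfg)
#' @export
microgambi_config <- function(weight_egi = 0, weight_egiii = 6,
                              class_boundaries = c(1.2, 3.3, 4.3, 5.5),
                              denominator_policy = c("assigned_only", "all_reads"),
                              unmatched_warn_threshold = 20) {
  denominator_policy <- match.arg(denominator_policy)
  stopifnot(
    is.numeric(weight_egi), length(weight_egi) == 1, weight_egi >= 0,
    is.numeric(weight_egiii), length(weight_egiii) == 1,
    is.numeric(class_boundaries), length(class_boundaries) == 4,
    is.numeric(unmatched_warn_threshold), length(unmatched_warn_threshold) == 1
  )
  if (!(weight_egi < weight_egiii)) {
    rlang::abort("weight_egi must be strictly less than weight_egiii")
  }
  if (any(diff(class_boundaries) <= 0)) {
    rlang::abort("class_boundaries must be strictly increasing")
  }
  if (class_boundaries[1] <= weight_egi || class_boundaries[4] >= weight_egiii) {
    rlang::abort("class_boundaries must lie strictly inside [weight_egi, weight_egiii]")
  }
  structure(
    list(
      weight_egi = weight_egi, weight_egiii = weight_egiii,
      class_boundaries = class_boundaries,
      denominator_policy = denominator_policy,
      unmatched_warn_threshold = unmatched_warn_threshold
    ),
    class = "microgambi_config"
  )
}

#' @export
print.microgambi_config <- function(x, ...) {
  cat(sprintf(
    paste0("<microgambi_config> index = (%g*f_EGI + %g*f_EGIII)/100;",
           " boundaries %s; denominator %s; coverage warn > %g%%\n"),
    x$weight_egi, x$weight_egiii,
    paste(x$class_boundaries, collapse = " / "),
    x$denominator_policy, x$unmatched_warn_threshold
  ))
  invisible(x)
}

#' Per-station read totals and richness
#'
#' For each station: the total number of reads (the column sum) and the
#' number of taxa, counting taxa with at least one read in that column.
#'
#' @param tbl An abundance tibble (see [read_abundance_table()]).
#' @param stations Station ids to report; default all, in table order.
#' @return Tibble with columns `station`, `total_reads`, `n_taxa`.
#' @export
station_totals <- function(tbl, stations = NULL) {
  validate_abundance(tbl)
  stations <- resolve_stations(tbl, stations)
  purrr::map_dfr(stations, function(s) {
    x <- tbl[[s]]
    tibble::tibble(station = s, total_reads = sum(x), n_taxa = sum(x > 0))
  })
}

resolve_stations <- function(tbl, stations) {
  all_ids <- station_ids(tbl)
  if (is.null(stations)) return(all_ids)
  missing <- setdiff(stations, all_ids)
  if (length(missing) > 0) {
    rlang::abort(sprintf("unknown station id(s): %s",
                         paste(missing, collapse = ", ")))
  }
  stations
}

#' Shannon-Wiener diversity in bits
#'
#' `H' = -sum(p_i * log2(p_i))` over taxa with positive counts, with
#' `p_i = count_i / total`. Using the base-2 logarithm the result is in
#' bits and bounded by `log2(richness)`.
#'
#' @param counts Non-negative numeric vector of read counts for one station.
#' @return H' in bits (a single non-negative number).
#' @examples
#' shannon_diversity(c(5, 5, 5, 5)) # 2 bits
#' shannon_diversity(c(2, 1, 1))    # 1.5 bits
#' @export
shannon_diversity <- function(counts) {
  if (!is.numeric(counts) || any(is.na(counts)) || any(counts < 0)) {
    rlang::abort("counts must be non-negative numbers with no missing values")
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0) {
    rlang::abort("Shannon diversity is undefined for an all-zero count vector")
  }
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Partition station reads by ecological group
#'
#' Routes every taxon with reads at a station into exactly one of four
#' categories — EGI, EGIII, not assigned (in the list, unknown function),
#' not in list (absent from the reference) — and sums its reads there.
#' The four read sums conserve the station total exactly; zero-count taxa
#' contribute nothing and are listed nowhere.
#'
#' @inheritParams station_totals
#' @param ref A `taxa_reference` from [read_taxa_reference()].
#' @param genus_fallback Passed to [lookup_taxon()].
#' @return Tibble with one row per station: `station`, read sums
#'   `reads_egi`, `reads_egiii`, `reads_not_assigned`, `reads_not_in_list`,
#'   and list-columns `taxa_egi`, `taxa_egiii`, `taxa_not_assigned`,
#'   `taxa_not_in_list` holding the taxon names in each category.
#' @export
partition_reads <- function(tbl, ref, stations = NULL, genus_fallback = FALSE) {
  validate_abundance(tbl)
  stations <- resolve_stations(tbl, stations)
  cat_map <- lookup_taxon(ref, tbl$taxon, genus_fallback = genus_fallback)$category
  purrr::map_dfr(stations, function(s) {
    x <- tbl[[s]]
    present <- x > 0
    sum_cat <- function(lv) sum(x[present & cat_map == lv])
    list_cat <- function(lv) list(tbl$taxon[present & cat_map == lv])
    tibble::tibble(
      station = s,
      reads_egi = sum_cat("EGI"),
      reads_egiii = sum_cat("EGIII"),
      reads_not_assigned = sum_cat("not assigned"),
      reads_not_in_list = sum_cat("not in list"),
      taxa_egi = list_cat("EGI"),
      taxa_egiii = list_cat("EGIII"),
      taxa_not_assigned = list_cat("not assigned"),
      taxa_not_in_list = list_cat("not in list")
    )
  })
}

#' Ecological-group fractions feeding the index
#'
#' Converts a read partition into the two percentages the index is built
#' from. Under `"assigned_only"` the denominator is EGI + EGIII reads, so
#' the two fractions sum to exactly 100; when no assigned reads exist the
#' result is undefined (`NA`, with a reason). Under `"all_reads"` the
#' denominator is the station total.
#'
#' @param partition Tibble from [partition_reads()] (read-sum columns used).
#' @param policy `"assigned_only"` (default) or `"all_reads"`.
#' @return `partition` with columns `f_egi`, `f_egiii` (percentages, `NA`
#'   when undefined) and `f_reason` (`NA` or `"no assigned reads"` /
#'   `"no reads"`) appended.
#' @export
eg_fractions <- function(partition, policy = c("assigned_only", "all_reads")) {
  policy <- match.arg(policy)
  assigned <- partition$reads_egi + partition$reads_egiii
  total <- assigned + partition$reads_not_assigned + partition$reads_not_in_list
  denom <- if (policy == "assigned_only") assigned else total
  ok <- denom > 0
  dplyr::mutate(
    partition,
    f_egi = ifelse(ok, 100 * partition$reads_egi / denom, NA_real_),
    f_egiii = ifelse(ok, 100 * partition$reads_egiii / denom, NA_real_),
    f_reason = dplyr::case_when(
      ok ~ NA_character_,
      total == 0 ~ "no reads",
      TRUE ~ "no assigned reads"
    )
  )
}

#' The biotic index from the two ecological-group fractions
#'
#' `index = (weight_egi * f_egi + weight_egiii * f_egiii) / 100`: affine in
#' `f_egiii`, equal to `weight_egi` when the community is all-sensitive and
#' to `weight_egiii` when all-tolerant.
#'
#' @param f_egi,f_egiii Percentages in `[0, 100]` (vectors recycle; `NA`
#'   propagates as an undefined index).
#' @param config A [microgambi_config()].
#' @return Numeric vector of index values in
#'   `[weight_egi, weight_egiii]`.
#' @export
microgambi_index <- function(f_egi, f_egiii, config = microgambi_config()) {
  stopifnot(inherits(config, "microgambi_config"))
  if (any(f_egi < 0, na.rm = TRUE) || any(f_egiii < 0, na.rm = TRUE)) {
    rlang::abort("group fractions must be non-negative percentages")
  }
  if (any(f_egi > 100, na.rm = TRUE) || any(f_egiii > 100, na.rm = TRUE)) {
    rlang::abort("group fractions are percentages and cannot exceed 100")
  }
  (config$weight_egi * f_egi + config$weight_egiii * f_egiii) / 100
}

#' Map index values to the five ecological status classes
#'
#' The index range is cut right-closed: `[weight_egi, b1]` is high,
#' `(b1, b2]` good, `(b2, b3]` moderate, `(b3, b4]` poor, and
#' `(b4, weight_egiii]` bad — every valid index value gets exactly one
#' class, and a larger index never maps to a better class. An exact tie on
#' a boundary therefore takes the better class. `NA` index values (no
#' assigned reads) classify as `"unclassifiable"`.
#'
#' @param index Numeric vector of index values.
#' @param config A [microgambi_config()].
#' @return Factor with levels high, good, moderate, poor, bad,
#'   unclassifiable.
#' @export
classify_status <- function(index, config = microgambi_config()) {
  stopifnot(inherits(config, "microgambi_config"))
  lo <- config$weight_egi
  hi <- config$weight_egiii
  tol <- 1e-9 * max(1, abs(hi))
  out_of_range <- !is.na(index) & (index < lo - tol | index > hi + tol)
  if (any(out_of_range)) {
    rlang::abort(sprintf(
      "index value %g outside the valid range [%g, %g]",
      index[out_of_range][1], lo, hi
    ))
  }
  clamped <- pmin(pmax(index, lo), hi)
  cls <- cut(clamped, breaks = c(lo, config$class_boundaries, hi),
             labels = STATUS_LEVELS[1:5], right = TRUE, include.lowest = TRUE)
  cls <- as.character(cls)
  cls[is.na(index)] <- "unclassifiable"
  factor(cls, levels = STATUS_LEVELS)
}

#' Assess every station of an abundance table
#'
#' Composes the per-station computations end to end: totals and richness,
#' Shannon-Wiener diversity (bits), the read partition by ecological
#' group, the group percentages under both denominators, the index, and
#' the status class. Richness and H' are computed over all taxa with
#' reads, including those not in the reference, exactly as the
#' spreadsheet template computes them on the raw data column. A station
#' with no EGI + EGIII reads gets an undefined index and status
#' `"unclassifiable"` instead of NaN arithmetic, and stations whose
#' unassigned plus unlisted reads exceed the configured threshold carry a
#' `low_assigned_coverage` flag.
#'
#' @inheritParams partition_reads
#' @param config A [microgambi_config()].
#' @return A `microgambi_assessment` tibble, one row per station in table
#'   order: `station`, `total_reads`, `n_taxa`, `shannon_h_bits`,
#'   percentages of the station total (`pct_egi`, `pct_egiii`,
#'   `pct_not_assigned`, `pct_not_in_list`), the index fractions under the
#'   configured denominator (`f_egi`, `f_egiii`), `index_value`, `status`,
#'   and a `flags` list-column. The configuration used is attached as the
#'   `config` attribute and echoed into written reports.
#' @examples
#' spec <- community_spec(n_stations = 3, egiii_read_fraction = c(0.1, 0.5, 0.9),
#'                        seed = 1)
#' ref <- generate_reference(spec)
#' tbl <- generate_communities(ref, spec)
#' assess_all(tbl, ref)
#' @export
assess_all <- function(tbl, ref, config = microgambi_config(),
                       genus_fallback = FALSE) {
  validate_abundance(tbl)
  stopifnot(inherits(ref, "taxa_reference"), inherits(config, "microgambi_config"))
  if (length(station_ids(tbl)) == 0) rlang::abort("no station columns to assess")

  totals <- station_totals(tbl)
  part <- partition_reads(tbl, ref, genus_fallback = genus_fallback)
  frac <- eg_fractions(part, policy = config$denominator_policy)

  h <- purrr::map_dbl(station_ids(tbl), function(s) {
    x <- tbl[[s]]
    if (sum(x) == 0) NA_real_ else shannon_diversity(x)
  })

  total <- totals$total_reads
  pct <- function(reads) ifelse(total > 0, 100 * reads / total, NA_real_)
  idx <- microgambi_index(frac$f_egi, frac$f_egiii, config)
  status <- classify_status(idx, config)

  pct_unmatched <- pct(part$reads_not_assigned + part$reads_not_in_list)
  flags <- purrr::pmap(
    list(pct_unmatched, is.na(idx), total),
    function(u, unclass, tot) {
      f <- character()
      if (tot == 0) f <- c(f, "no_reads")
      if (!is.na(u) && u > config$unmatched_warn_threshold) {
        f <- c(f, "low_assigned_coverage")
      }
      if (unclass && tot > 0) f <- c(f, "no_assigned_reads")
      f
    }
  )

  out <- tibble::tibble(
    station = totals$station,
    total_reads = total,
    n_taxa = totals$n_taxa,
    shannon_h_bits = h,
    pct_egi = pct(part$reads_egi),
    pct_egiii = pct(part$reads_egiii),
    pct_not_assigned = pct(part$reads_not_assigned),
    pct_not_in_list = pct(part$reads_not_in_list),
    f_egi = frac$f_egi,
    f_egiii = frac$f_egiii,
    index_value = idx,
    status = status,
    flags = flags
  )
  structure(out, config = config,
            class = c("microgambi_assessment", class(tibble::tibble())))
}

#' Assess a single station
#'
#' @inheritParams assess_all
#' @param station A station id present in `tbl`.
#' @return One-row `microgambi_assessment` tibble (see [assess_all()]).
#' @export
assess_station <- function(tbl, ref, station, config = microgambi_config(),
                           genus_fallback = FALSE) {
  stations <- resolve_stations(tbl, station)
  assess_all(tbl[, c("taxon", stations)], ref, config = config,
             genus_fallback = genus_fallback)
}

#' @export
tidy.microgambi_assessment <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$flags <- purrr::map_chr(out$flags, paste, collapse = ";")
  out
}

#' @export
glance.microgambi_assessment <- function(x, ...) {
  tibble::tibble(
    n_stations = nrow(x),
    n_classified = sum(x$status != "unclassifiable"),
    n_unclassifiable = sum(x$status == "unclassifiable"),
    mean_index = mean(x$index_value, na.rm = TRUE),
    min_index = suppressWarnings(min(x$index_value, na.rm = TRUE)),
    max_index = suppressWarnings(max(x$index_value, na.rm = TRUE)),
    mean_shannon_bits = mean(x$shannon_h_bits, na.rm = TRUE)
  )
}

#' Configuration attached to an assessment
#' @param x A `microgambi_assessment`.
#' @return The [microgambi_config()] the assessment was computed under.
#' @export
assessment_config <- function(x) {
  stopifnot(inherits(x, "microgambi_assessment"))
  attr(x, "config")
}
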