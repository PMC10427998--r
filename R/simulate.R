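#' Specification of a synthetic community experiment
#'
#' Describes a miniature reference list plus a set of station read columns
#' with known ecological-group composition, so the full assessment
#' pipeline can be exercised with a known answer. Per station, a fraction
#' `egiii_read_fraction` (pi) of the *assigned* reads is expected on EGIII
#' taxa and `1 - pi` on EGI taxa; separate pools of reads go to
#' not-assigned and not-in-list taxa. The analytic expectation of the
#' index under this model is [expected_index()].
#'
#' `dispersion` controls the sampling model: `0` produces the exact
#' expected counts (deterministically rounded so column sums are exact);
#' any positive value draws each station multinomially, with within-group
#' taxon weights perturbed by a symmetric Dirichlet whose concentration is
#' `1 / dispersion` (small values: nearly uniform; large values: a few
#' taxa dominate each group).
#'
#' @param n_stations Number of stations (columns).
#' @param egiii_read_fraction Expected EGIII fraction of assigned reads,
#'   one value per station (recycled from length 1); in `[0, 1]`.
#' @param n_taxa_egi,n_taxa_egiii,n_taxa_not_assigned,n_taxa_not_in_list
#'   Numbers of taxa in each pool (defaults 25, 25, 5, 5).
#' @param not_assigned_read_fraction,not_in_list_read_fraction Expected
#'   share of each station's total reads on the not-assigned and
#'   not-in-list pools (defaults 0.05 each); the assigned pool receives
#'   the remainder.
#' @param total_reads_per_station Reads per station column (default 10000).
#' @param dispersion Non-negative; see above (default 0.5).
#' @param seed Integer seed; generation is bit-for-bit reproducible.
#' @return A `community_spec` list.
#' @export
community_spec <- function(n_stations = 10,
                           egiii_read_fraction = 0.5,
                           n_taxa_egi = 25, n_taxa_egiii = 25,
                           n_taxa_not_assigned = 5, n_taxa_not_in_list = 5,
                           not_assigned_read_fraction = 0.05,
                           not_in_list_read_fraction = 0.05,
                           total_reads_per_station = 10000,
                           dispersion = 0.5,
                           seed = 1L) {
  pi <- rep_len(egiii_read_fraction, n_stations)
  stopifnot(
    n_stations >= 1,
    all(pi >= 0 & pi <= 1),
    n_taxa_egi >= 0, n_taxa_egiii >= 0,
    n_taxa_not_assigned >= 0, n_taxa_not_in_list >= 0,
    not_assigned_read_fraction >= 0, not_in_list_read_fraction >= 0,
    not_assigned_read_fraction + not_in_list_read_fraction <= 1,
    total_reads_per_station >= 0, dispersion >= 0
  )
  structure(
    list(
      n_stations = as.integer(n_stations),
      egiii_read_fraction = pi,
      n_taxa_egi = as.integer(n_taxa_egi),
      n_taxa_egiii = as.integer(n_taxa_egiii),
      n_taxa_not_assigned = as.integer(n_taxa_not_assigned),
      n_taxa_not_in_list = as.integer(n_taxa_not_in_list),
      not_assigned_read_fraction = not_assigned_read_fraction,
      not_in_list_read_fraction = not_in_list_read_fraction,
      total_reads_per_station = as.integer(total_reads_per_station),
      dispersion = dispersion,
      seed = as.integer(seed)
    ),
    class = "community_spec"
  )
}

# Deterministic synthetic names: every 5th taxon in a pool is a
# genus-level entry (no epithet), so the "Genus sp." community labels and
# genus-fallback matching paths get exercised.
synthetic_names <- function(prefix, n) {
  if (n == 0) return(character())
  i <- seq_len(n)
  ifelse(i %% 5 == 0,
         sprintf("%s%03d", prefix, i),
         sprintf("%s%03d species%03d", prefix, i, i))
}

#' Generate a miniature taxa reference with known composition
#'
#' Synthesizes unique taxon names routed into EGI / EGIII / not assigned
#' per the spec; not-in-list taxa are generated only in the community
#' tables, never in the reference. The result passes reference validation
#' with zero issues.
#'
#' @param spec A [community_spec()].
#' @return A `taxa_reference` (see [read_taxa_reference()]).
#' @export
generate_reference <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  name <- c(
    synthetic_names("Sensigenus", spec$n_taxa_egi),
    synthetic_names("Tolerigenus", spec$n_taxa_egiii),
    synthetic_names("Ignotigenus", spec$n_taxa_not_assigned)
  )
  eg <- c(
    rep("EGI", spec$n_taxa_egi),
    rep("EGIII", spec$n_taxa_egiii),
    rep("not assigned", spec$n_taxa_not_assigned)
  )
  n <- length(name)
  rec <- tibble::tibble(
    row_number = seq_len(n),
    name = name,
    name_key = tolower(name),
    ncbi_accession = NA_character_,
    worms_accession = NA_character_,
    eg = factor(eg, levels = EG_LEVELS),
    evidence_links = NA_character_,
    literature = "synthetic fixture",
    comments = NA_character_
  )
  if (n == 0) rec <- empty_reference_records()
  new_taxa_reference(rec, empty_issues(),
                     sprintf("synthetic-seed%d", spec$seed))
}

# Largest-remainder rounding: integer vector summing exactly to `total`,
# proportional to `p`.
round_conserving <- function(p, total) {
  if (length(p) == 0) return(integer())
  if (sum(p) == 0) return(integer(length(p)))
  raw <- p / sum(p) * total
  base <- floor(raw)
  short <- total - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate station read-count columns for a synthetic reference
#'
#' For each station the expected read allocation is: `not_assigned` and
#' `not_in_list` shares to their pools, and of the remaining (assigned)
#' reads a fraction pi to EGIII taxa and `1 - pi` to EGI taxa, uniform
#' within each group. With `dispersion = 0` the station column is exactly
#' that expectation (largest-remainder rounding); with `dispersion > 0`
#' the column is one multinomial draw with Dirichlet-perturbed
#' within-group weights. Column sums equal `total_reads_per_station`
#' exactly in both cases.
#'
#' Community labels deliberately decorate the reference names the way
#' classifier outputs do: genus-level taxa appear with a trailing " sp."
#' and some labels use underscores, so the matching normalization is
#' exercised end to end.
#'
#' @param ref The `taxa_reference` from [generate_reference()] for the
#'   same spec.
#' @param spec A [community_spec()].
#' @return An abundance tibble (`taxon` column plus `ST01`, `ST02`, ...).
#' @export
generate_communities <- function(ref, spec) {
  stopifnot(inherits(ref, "taxa_reference"), inherits(spec, "community_spec"))
  expected <- spec$n_taxa_egi + spec$n_taxa_egiii + spec$n_taxa_not_assigned
  if (nrow(ref) != expected) {
    rlang::abort("reference does not match spec (taxon pool sizes differ)")
  }

  labels <- c(decorate_labels(ref$name),
              decorate_labels(synthetic_names("Novigenus", spec$n_taxa_not_in_list)))
  pool <- c(as.character(ref$eg), rep("not in list", spec$n_taxa_not_in_list))
  n_taxa <- length(labels)
  share <- c(
    "EGI" = 1 - spec$not_assigned_read_fraction - spec$not_in_list_read_fraction,
    "not assigned" = spec$not_assigned_read_fraction,
    "not in list" = spec$not_in_list_read_fraction
  )

  counts <- withr::with_seed(spec$seed, {
    vapply(seq_len(spec$n_stations), function(j) {
      pi_j <- spec$egiii_read_fraction[j]
      group_share <- c(
        "EGI" = unname(share["EGI"]) * (1 - pi_j),
        "EGIII" = unname(share["EGI"]) * pi_j,
        "not assigned" = unname(share["not assigned"]),
        "not in list" = unname(share["not in list"])
      )
      p <- numeric(n_taxa)
      for (g in names(group_share)) {
        in_g <- pool == g
        k <- sum(in_g)
        if (k == 0 || group_share[[g]] == 0) next
        w <- if (spec$dispersion > 0) {
          d <- stats::rgamma(k, shape = 1 / spec$dispersion, rate = 1)
          if (sum(d) == 0) rep(1 / k, k) else d / sum(d)
        } else {
          rep(1 / k, k)
        }
        p[in_g] <- group_share[[g]] * w
      }
      if (spec$dispersion > 0) {
        as.integer(stats::rmultinom(1, spec$total_reads_per_station, p))
      } else {
        round_conserving(p, spec$total_reads_per_station)
      }
    }, integer(n_taxa))
  })
  counts <- matrix(counts, nrow = n_taxa)

  out <- tibble::as_tibble(
    cbind(data.frame(taxon = labels, stringsAsFactors = FALSE),
          as.data.frame(counts)),
    .name_repair = "minimal"
  )
  names(out) <- c("taxon", sprintf("ST%02d", seq_len(spec$n_stations)))
  out
}

# "Genus005" -> "Genus005 sp."; every 7th label gets underscores
decorate_labels <- function(name) {
  out <- ifelse(grepl(" ", name), name, paste0(name, " sp."))
  i <- seq_along(out)
  out[i %% 7 == 0] <- gsub(" ", "_", out[i %% 7 == 0])
  out
}

#' Analytic expectation of the index under the generator
#'
#' With an expected EGIII fraction `pi` of assigned reads, the expected
#' index under the `assigned_only` denominator is
#' `weight_egi + (weight_egiii - weight_egi) * pi` — the oracle used in
#' parameter-recovery checks.
#'
#' @param pi Expected EGIII fraction(s) of assigned reads, in `[0, 1]`.
#' @param config A [microgambi_config()].
#' @return Numeric vector of expected index values.
#' @export
expected_index <- function(pi, config = microgambi_config()) {
  stopifnot(inherits(config, "microgambi_config"))
  if (any(pi < 0 | pi > 1, na.rm = TRUE)) {
    rlang::abort("pi must lie in [0, 1]")
  }
  config$weight_egi + (config$weight_egiii - config$weight_egi) * pi
}
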