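---
title: "Assessing marine ecological status from microbial read counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing marine ecological status from microbial read counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microgambi)
```

## The assessment model

Benthic biotic indices of the AMBI family score a community by how its
abundance is split between pollution-sensitive and pollution-tolerant
organisms. The microbial variant implemented here simplifies the grouping
to two responses: taxa not associated with pollution inputs form group
**EGI** (sensitive and indifferent), taxa associated with pollution —
organic enrichment, anoxic sediments, wastewater, hydrocarbon degradation,
potential pathogens — form group **EGIII** (tolerant and opportunistic).
Assigning a taxon to a group is a human literature-curation task; this
package only consumes the resulting reference list, it never infers
assignments.

Given read counts for one station, let $f_\mathrm{EGI}$ and
$f_\mathrm{EGIII}$ be the percentages of reads on each group. The index is

$$\mathrm{index} \;=\; \frac{w_\mathrm{I}\, f_\mathrm{EGI} + w_\mathrm{III}\, f_\mathrm{EGIII}}{100},
\qquad w_\mathrm{I}=0,\; w_\mathrm{III}=6,$$

an affine function of the tolerant fraction ranging over
$[w_\mathrm{I}, w_\mathrm{III}]$. Status classes follow the AMBI boundary
convention on that range: high $[0, 1.2]$, good $(1.2, 3.3]$, moderate
$(3.3, 4.3]$, poor $(4.3, 5.5]$, bad $(5.5, 6]$.

Alongside the index, each station is summarized the way the original
spreadsheet template does: total reads (column sum), number of taxa (cells
with reads), Shannon–Wiener diversity $H' = -\sum_i p_i \log_2 p_i$ in
bits, and the read percentages in the four matching categories — EGI,
EGIII, *not assigned* (in the list, unknown function) and *not in list*
(absent from the reference; a different statement than "unknown
function").

## Parameters that matter

* **Weights** `weight_egi = 0`, `weight_egiii = 6` (dimensionless): the
  endpoints of the index scale. Configurable because list revisions and
  related indices use the same machinery with other coefficients; every
  report echoes the values used.
* **Class boundaries** `c(1.2, 3.3, 4.3, 5.5)` (index units): must be
  strictly increasing and lie inside the weight interval; validated at
  construction.
* **Denominator policy** (`assigned_only`, default, vs `all_reads`):
  whether the group fractions feeding the index are renormalized over
  assigned (EGI + EGIII) reads or taken over the station total. The
  template text does not pin this down, so it is an explicit option; we
  default to `assigned_only` because the AMBI lineage computes its group
  fractions over classified individuals, and because it makes the index
  invariant to the size of the unclassified pool. Both percentage sets
  appear in the output either way.
* **Coverage threshold** `unmatched_warn_threshold = 20` (% of reads):
  stations whose *not assigned* + *not in list* reads exceed it are
  flagged `low_assigned_coverage` — with most reads unclassified the index
  rests on a thin slice of the community and users should treat the
  status with caution (and ideally contribute the missing taxa to the
  curated list).

## Name normalization and matching

Classifier outputs and the curated list disagree in mechanical ways, so
matching runs on a normalized key: whitespace trimmed, runs of whitespace
and underscores collapsed to one space, a trailing "sp." / "sp" / "spp."
token dropped (genus-level list entries carry no such suffix), and
case-folded comparison. Normalization is idempotent, and display names
keep their original casing. An optional second pass (`genus_fallback`,
off by default) retries unmatched queries with their genus token alone;
it is off by default because a genus-level hit silently generalizes a
species-level observation, which should be the user's decision.

Reference parsing collects structural problems as typed issues instead of
failing fast: short rows, empty names, unrecognized group codes,
duplicates. Duplicated names with the same group keep the first record
(warning); with conflicting groups the index would be ambiguous, so the
conflict is an error and the later record is dropped (strict mode aborts
instead). Blank group cells mean *not assigned*, matching how the list
encodes unknown function.

## Numerical choices

* Counts must be integers; relative abundances are rejected at parse time
  since richness and $H'$ would be corrupted.
* $H'$ sums only over taxa with positive counts; an all-zero column is a
  typed error, and a station with zero assigned reads gets an `NA` index
  and `unclassifiable` status rather than NaN arithmetic.
* Class intervals are right-closed with the best class closed at the
  minimum, so an index exactly on a boundary takes the better class; ties
  cannot be resolved from the published boundary values, so the
  convention is documented and tested rather than implicit.
* Out-of-range index values error; values within $10^{-9}$ of the range
  endpoints are clamped before classification to absorb floating-point
  slack.
* Percentages and $H'$ are carried at full precision; reports add a
  2-decimal display column for the index but never round the stored
  values.

## The synthetic community generator

`community_spec()` / `generate_reference()` / `generate_communities()`
build seeded, bit-for-bit reproducible fixtures: a miniature reference
with known composition and station columns with a known expected EGIII
read fraction $\pi$ of the assigned reads. The expected index is then the
affine map `expected_index(pi)` $= w_\mathrm{I} + (w_\mathrm{III} -
w_\mathrm{I})\pi$, which is the oracle for parameter-recovery checks.

Default conditions, chosen once as a plausible coastal metabarcoding
profile: 10,000 reads per station; 25 EGI, 25 EGIII, 5 not-assigned and 5
not-in-list taxa; 5% of reads each on the not-assigned and not-in-list
pools. `dispersion = 0` produces the exact expected counts
(largest-remainder rounding, so column totals are conserved); any
positive value draws each station from a multinomial whose within-group
taxon weights come from a symmetric Dirichlet with concentration
`1/dispersion` (default 0.5: mildly uneven communities). Generated labels
deliberately decorate the reference names with " sp." suffixes and
underscores so the matching path is exercised end to end.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: phylogenetically correlated abundances,
calibrated zero inflation, sequencing error, compositional bias between
stations, or any realism in the taxon names. It validates the arithmetic
and plumbing of the assessment, not the ecology.

Test and verification problem sizes were picked to keep the suite quick
while leaving Monte-Carlo error far below the effects checked: 200
stations per mixing fraction for recovery (standard error of the mean
index ≈ 0.01 index units at $\pi = 0.5$), 100 random matrices for read
conservation, $10^3$–$10^4$ cases for the normalization and diversity
property checks.

## Design notes

* The package is tidyverse-shaped: readers return tibbles, `assess_all()`
  returns a tibble subclass with `tidy()`, `glance()` and `autoplot()`
  methods, and all per-station quantities are plain columns.
* Richness and $H'$ are computed over **all** taxa with reads, including
  those absent from the reference, because the template computes them on
  the raw data column before any matching.
* The reference's evidence columns (accessions, links, literature,
  comments) are carried verbatim and never resolved against NCBI or
  WoRMS; they are provenance, not computation.
* The header row of both input formats defaults to "present"; the
  reference list's layout is described by column position, so a
  header-less variant is handled by a flag rather than detection.

## Limitations

* Group assignment quality is inherited entirely from the reference list;
  the package cannot detect a wrong assignment, only a missing one.
* The index says nothing about *which* pressure drives a poor status;
  interpreting gradients needs external pressure data.
* No confidence intervals are attached to the status class; the class is
  a deterministic function of the observed read split.
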