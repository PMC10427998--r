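Package: microgambi
Title: Microbial Biotic Index for Marine Ecological Status Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the microgAMBI biotic index from 16S metabarcoding
    read-count tables. Given a curated reference list assigning microbial
    taxa to ecological groups (EGI, sensitive/indifferent to pollution;
    EGIII, tolerant/opportunistic), the package normalizes and matches
    taxon names, partitions per-station reads by ecological group,
    computes richness and Shannon-Wiener diversity (log2), evaluates the
    weighted index over the relative abundances of the two groups, and
    classifies each station into one of five ecological status classes
    (high, good, moderate, poor, bad). Includes a seeded synthetic
    community generator for testing, tidy accessors, plotting helpers,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
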