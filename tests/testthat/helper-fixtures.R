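# Builders for tiny in-code fixtures shared across test files.

# A reference TSV (8 columns, header) from name/EG pairs.
ref_lines <- function(names, egs) {
  header <- "no\ttaxon\tncbi\tworms\tEG\tlinks\tliterature\tcomments"
  rows <- sprintf("%d\t%s\t\t\t%s\t\t\t", seq_along(names), names, egs)
  c(header, rows)
}

make_reference <- function(names, egs, ...) {
  read_taxa_reference(ref_lines(names, egs), ...)
}

# The standard 3-taxon reference most index tests use.
demo_reference <- function() {
  make_reference(
    c("Desulfobacter", "Vibrio", "Ignotus"),
    c("I", "III", "not assigned")
  )
}

# An abundance tibble from a named list of station count vectors.
make_abundance <- function(taxa, ...) {
  cols <- list(...)
  tibble::as_tibble(c(list(taxon = taxa), cols))
}

random_counts <- function(n, max = 50) {
  as.integer(sample.int(max + 1, n, replace = TRUE) - 1L)
}

random_string <- function(n_chars) {
  pool <- c(letters, LETTERS, " ", "_", ".", "0":"9")
  paste(sample(pool, n_chars, replace = TRUE), collapse = "")
}
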