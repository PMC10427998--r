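test_that("station totals are column sums and positive-cell counts", {
  tbl <- make_abundance(c("A", "B", "C"),
                        S1 = c(10L, 0L, 5L), S2 = c(2L, 1L, 1L), S3 = c(0L, 0L, 0L))
  tot <- station_totals(tbl)
  expect_equal(tot$total_reads, c(15L, 4L, 0L))
  expect_equal(tot$n_taxa, c(2L, 3L, 0L))
  expect_error(station_totals(tbl, "nope"), "unknown station")
})

test_that("Shannon diversity matches closed forms and stays within bounds", {
  expect_equal(shannon_diversity(7), 0)
  expect_equal(shannon_diversity(c(5, 5, 5, 5)), 2)
  expect_equal(shannon_diversity(c(2, 1, 1)), 1.5)
  expect_error(shannon_diversity(c(0, 0)), "undefined")
  expect_error(shannon_diversity(c(-1, 2)))

  set.seed(101)
  for (i in 1:50) {
    x <- random_counts(sample(2:40, 1))
    if (sum(x) == 0) x[1] <- 1L
    h <- shannon_diversity(x)
    expect_gte(h, 0)
    expect_lte(h, log2(sum(x > 0)) + 1e-12)
  }
})

test_that("Shannon diversity agrees with vegan's independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(202)
  for (i in 1:50) {
    x <- random_counts(sample(2:60, 1), max = 500)
    if (sum(x) == 0) x[1] <- 7L
    expect_equal(shannon_diversity(x),
                 unname(vegan::diversity(x, index = "shannon", base = 2)),
                 tolerance = 1e-12)
  }
})

test_that("read partition routes every counted taxon into exactly one category", {
  ref <- demo_reference()
  tbl <- make_abundance(
    c("Desulfobacter", "Vibrio sp.", "Ignotus", "Mysterium"),
    S1 = c(60L, 40L, 0L, 0L),
    S2 = c(60L, 40L, 0L, 10L),
    S3 = c(0L, 0L, 25L, 0L)
  )
  p <- partition_reads(tbl, ref)
  expect_equal(p$reads_egi, c(60L, 60L, 0L))
  expect_equal(p$reads_egiii, c(40L, 40L, 0L))
  expect_equal(p$reads_not_assigned, c(0L, 0L, 25L))
  expect_equal(p$reads_not_in_list, c(0L, 10L, 0L))
  # zero-count taxa are listed nowhere
  expect_equal(p$taxa_egi[[1]], "Desulfobacter")
  expect_equal(p$taxa_not_in_list[[1]], character(0))
  expect_equal(p$taxa_not_in_list[[2]], "Mysterium")
  n_listed <- lengths(p$taxa_egi) + lengths(p$taxa_egiii) +
    lengths(p$taxa_not_assigned) + lengths(p$taxa_not_in_list)
  expect_equal(n_listed, station_totals(tbl)$n_taxa)
})

test_that("partition read sums conserve column totals on random matrices", {
  set.seed(303)
  for (i in 1:25) {
    spec <- community_spec(
      n_stations = sample(1:5, 1),
      egiii_read_fraction = runif(1),
      total_reads_per_station = sample(100:2000, 1),
      dispersion = runif(1, 0, 2),
      seed = sample.int(1e6, 1)
    )
    ref <- generate_reference(spec)
    tbl <- generate_communities(ref, spec)
    p <- partition_reads(tbl, ref)
    sums <- p$reads_egi + p$reads_egiii + p$reads_not_assigned + p$reads_not_in_list
    expect_equal(sums, station_totals(tbl)$total_reads)
  }
})

test_that("group fractions renormalize over assigned reads or the full total", {
  p <- tibble::tibble(reads_egi = c(60L, 60L, 0L, 0L),
                      reads_egiii = c(40L, 40L, 0L, 0L),
                      reads_not_assigned = c(0L, 0L, 50L, 0L),
                      reads_not_in_list = c(0L, 100L, 0L, 0L))
  f <- eg_fractions(p, "assigned_only")
  expect_equal(f$f_egi, c(60, 60, NA, NA))
  expect_equal(f$f_egiii, c(40, 40, NA, NA))
  expect_equal(f$f_reason, c(NA, NA, "no assigned reads", "no reads"))
  expect_equal(f$f_egi[1:2] + f$f_egiii[1:2], c(100, 100))

  g <- eg_fractions(p, "all_reads")
  expect_equal(g$f_egi[2], 100 * 60 / 200)
  expect_equal(g$f_egiii[2], 100 * 40 / 200)
})

test_that("the index is the stated affine form over its whole range", {
  cfg <- microgambi_config()
  expect_equal(microgambi_index(100, 0, cfg), 0)
  expect_equal(microgambi_index(0, 100, cfg), 6)
  expect_equal(microgambi_index(50, 50, cfg), 3)
  # brute-force recomputation at a grid of split points
  f3 <- seq(0, 100, length.out = 101)
  brute <- vapply(f3, function(f) (cfg$weight_egi * (100 - f) +
                                     cfg$weight_egiii * f) / 100, numeric(1))
  expect_equal(microgambi_index(100 - f3, f3, cfg), brute, tolerance = 1e-14)
  expect_error(microgambi_index(-1, 50, cfg), "non-negative")
  expect_error(microgambi_index(0, 101, cfg), "exceed")

  # non-default weights shift both endpoints
  cfg2 <- microgambi_config(weight_egi = 1, weight_egiii = 5,
                            class_boundaries = c(1.5, 2.5, 3.5, 4.5))
  expect_equal(microgambi_index(100, 0, cfg2), 1)
  expect_equal(microgambi_index(0, 100, cfg2), 5)
})

test_that("classification is total, monotone, right-closed at boundaries", {
  cfg <- microgambi_config()
  expect_equal(as.character(classify_status(0, cfg)), "high")
  expect_equal(as.character(classify_status(6, cfg)), "bad")
  b <- cfg$class_boundaries
  eps <- 1e-9
  expect_equal(as.character(classify_status(b[2], cfg)), "good")
  expect_equal(as.character(classify_status(b[2] + 1e-6, cfg)), "moderate")
  expect_equal(as.character(classify_status(b, cfg)),
               c("high", "good", "moderate", "poor"))

  sweep <- seq(0, 6, length.out = 2001)
  cls <- classify_status(sweep, cfg)
  expect_false(any(is.na(cls)))
  expect_false(any(cls == "unclassifiable"))
  ranks <- as.integer(cls)
  expect_true(all(diff(ranks) >= 0)) # larger index never maps to a better class

  expect_error(classify_status(6.5, cfg), "outside")
  expect_equal(as.character(classify_status(NA_real_, cfg)), "unclassifiable")
})

test_that("assessment composes the parts and matches hand computation", {
  ref <- demo_reference()
  tbl <- make_abundance(c("Desulfobacter", "Vibrio"),
                        S1 = c(60L, 40L), S2 = c(60L, 40L))
  a <- assess_all(tbl, ref)
  expect_s3_class(a, "microgambi_assessment")
  expect_equal(a$total_reads, c(100L, 100L))
  expect_equal(a$n_taxa, c(2L, 2L))
  expect_equal(a$shannon_h_bits,
               rep(-(0.6 * log2(0.6) + 0.4 * log2(0.4)), 2))
  expect_equal(a$f_egi, c(60, 60))
  expect_equal(a$index_value, rep((0 * 60 + 6 * 40) / 100, 2))
  expect_equal(as.character(a$status), c("good", "good"))
  expect_equal(a$flags, list(character(0), character(0)))
  # identical columns, identical assessments
  expect_equal(as.data.frame(a[1, -1]), as.data.frame(a[2, -1]))
})

test_that("stations with no assigned reads are unclassifiable, flagged, no NaN", {
  ref <- demo_reference()
  tbl <- make_abundance(c("Ignotus", "Mysterium"),
                        S1 = c(30L, 70L), S2 = c(10L, 0L))
  a <- expect_silent(assess_all(tbl, ref))
  expect_equal(as.character(a$status), rep("unclassifiable", 2))
  expect_true(all(is.na(a$index_value)))
  expect_false(any(is.nan(unlist(a[, c("pct_egi", "pct_egiii")]))))
  expect_true(all(vapply(a$flags, function(f) "low_assigned_coverage" %in% f,
                         logical(1))))
  expect_true(all(vapply(a$flags, function(f) "no_assigned_reads" %in% f,
                         logical(1))))
})

test_that("the coverage flag trips exactly at the configured threshold", {
  ref <- demo_reference()
  tbl <- make_abundance(c("Desulfobacter", "Mysterium"),
                        S1 = c(80L, 20L), S2 = c(79L, 21L))
  a <- assess_all(tbl, ref) # default threshold: 20% unmatched
  expect_equal(a$flags[[1]], character(0)) # exactly 20% does not trip
  expect_equal(a$flags[[2]], "low_assigned_coverage")
})

test_that("percentage identities hold whenever a station has reads", {
  spec <- community_spec(n_stations = 6, egiii_read_fraction = runif(6),
                         dispersion = 1, seed = 17)
  ref <- generate_reference(spec)
  a <- assess_all(generate_communities(ref, spec), ref)
  expect_equal(a$pct_egi + a$pct_egiii + a$pct_not_assigned + a$pct_not_in_list,
               rep(100, 6), tolerance = 1e-9)
  expect_equal(a$f_egi + a$f_egiii, rep(100, 6), tolerance = 1e-9)
})

test_that("scaling all counts of a station changes no assessment output", {
  ref <- demo_reference()
  tbl1 <- make_abundance(c("Desulfobacter", "Vibrio", "Mysterium"),
                         S1 = c(6L, 3L, 1L))
  tbl2 <- tbl1
  tbl2$S1 <- tbl2$S1 * 37L
  a1 <- tidy(assess_all(tbl1, ref))
  a2 <- tidy(assess_all(tbl2, ref))
  same <- c("n_taxa", "shannon_h_bits", "pct_egi", "pct_egiii", "f_egi",
            "f_egiii", "index_value", "status", "flags")
  expect_equal(a1[same], a2[same])
})

test_that("assess_station subsets and station permutation permutes outputs", {
  spec <- community_spec(n_stations = 4, egiii_read_fraction = c(0.1, 0.4, 0.7, 1),
                         seed = 23)
  ref <- generate_reference(spec)
  tbl <- generate_communities(ref, spec)
  full <- assess_all(tbl, ref)
  one <- assess_station(tbl, ref, "ST03")
  expect_equal(as.data.frame(one), as.data.frame(full[3, ]))

  perm <- c(1, 4, 2, 5, 3) # taxon col + shuffled stations
  shuffled <- assess_all(tbl[, perm], ref)
  expect_equal(as.data.frame(shuffled), as.data.frame(full[c(3, 1, 4, 2), ]))
  expect_error(assess_all(tbl[, 1, drop = FALSE], ref), "station")
})

test_that("denominator policy changes the index only when unmatched reads exist", {
  ref <- demo_reference()
  tbl <- make_abundance(c("Desulfobacter", "Vibrio", "Mysterium"),
                        S1 = c(60L, 40L, 100L))
  assigned <- assess_all(tbl, ref, microgambi_config(denominator_policy = "assigned_only"))
  all_reads <- assess_all(tbl, ref, microgambi_config(denominator_policy = "all_reads"))
  expect_equal(assigned$index_value, 2.4) # 40/(60+40) * 6
  expect_equal(all_reads$index_value, 6 * 40 / 200)
})

test_that("tidy and glance summarize an assessment", {
  spec <- community_spec(n_stations = 3, egiii_read_fraction = c(0, 0.5, 1),
                         dispersion = 0, seed = 2)
  ref <- generate_reference(spec)
  a <- assess_all(generate_communities(ref, spec), ref)
  td <- tidy(a)
  expect_true(is.character(td$flags))
  g <- glance(a)
  expect_equal(g$n_stations, 3)
  expect_equal(g$n_unclassifiable, 0)
  expect_equal(g$min_index, 0)
  expect_equal(g$max_index, 6)
})

test_that("autoplot and composition plots build without error", {
  spec <- community_spec(n_stations = 3, egiii_read_fraction = c(0.2, 0.5, 0.8),
                         seed = 9)
  ref <- generate_reference(spec)
  a <- assess_all(generate_communities(ref, spec), ref)
  p1 <- ggplot2::autoplot(a)
  p2 <- plot_eg_composition(a)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p1))
  expect_no_error(ggplot2::ggplot_build(p2))
})
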