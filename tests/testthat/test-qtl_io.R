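test_that("map parsing computes cumulative positions by running sum", {
  map <- read_map_file(
    "chromosome\tmarker\tdistance_from_previous_cM\nc1\tM1\t0\nc1\tM2\t5.2\nc1\tM3\t3.1")
  expect_equal(map$position_cM, c(0, 5.2, 8.3))
  expect_equal(map_lengths(map)$length_cM, 8.3)

  single <- read_map_file(
    "chromosome\tmarker\tdistance_from_previous_cM\nc1\tM1\t0")
  expect_equal(map_lengths(single)$length_cM, 0)
})

test_that("map parsing rejects malformed files", {
  expect_error(read_map_file(
    "chromosome\tmarker\tdistance_from_previous_cM\nc1\tM1\t0\nc1\tM2\t-2"),
    "negative")
  expect_error(read_map_file(
    "chromosome\tmarker\tdistance_from_previous_cM\nc1\tM1\t0\nc1\tM1\t4"),
    "duplicate")
  expect_error(read_map_file(
    "chromosome\tmarker\tdistance_from_previous_cM\nc99\tM1\t0"),
    "unknown chromosome")
  expect_error(read_map_file(
    "chromosome\tmarker\tdistance_from_previous_cM\nc1\tM1\t3"),
    "distance 0")
})

test_that("map files round-trip through write and read", {
  spec <- synthetic_spec(n_chromosomes = 4)
  map <- generate_map(spec, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_map_file(map, path)
  back <- read_map_file(path)
  expect_equal(as.data.frame(back), as.data.frame(map))
})

test_that("QTL parsing stores empty numerics as missing, never zero", {
  txt <- paste(
    paste(qtl_file_cols <- c("map_name", "qtl_name", "study_id", "chromosome",
                             "trait", "lod", "r2", "method", "position_cM",
                             "ci_lo_cM", "ci_hi_cM", "flank_left",
                             "flank_right"), collapse = "\t"),
    "m1\tq1\tS1\tc3\tMicro\t3.2\t0.12\tCIM\t12.3\t8.0\t16.0\t\t",
    "m1\tq2\tS1\tc3\tFS\t\t\tMQM\t\t\t\tMk1\tMk2",
    sep = "\n")
  recs <- read_qtl_file(txt)
  expect_equal(recs$position_cM, c(12.3, NA))
  expect_equal(recs$ci_lo_cM, c(8, NA))
  expect_equal(recs$lod, c(3.2, NA))
  expect_equal(recs$flank_left, c(NA, "Mk1"))
  expect_equal(recs$trait, c("Micro", "FS"))
})

test_that("QTL parsing normalizes trait synonyms and flags unknown codes", {
  header <- paste(c("map_name", "qtl_name", "study_id", "chromosome", "trait",
                    "lod", "r2", "method", "position_cM", "ci_lo_cM",
                    "ci_hi_cM", "flank_left", "flank_right"), collapse = "\t")
  good <- paste(header,
                "m1\tq1\tS1\tc3\tMicronaire\t\t\tCIM\t5\t1\t9\t\t",
                "m1\tq2\tS1\tc3\tLeaf morph\t\t\tCIM\t8\t2\t12\t\t",
                sep = "\n")
  expect_equal(read_qtl_file(good)$trait, c("Micro", "LeafMorph"))

  bad <- paste(header, "m1\tq1\tS1\tc3\tXYZ\t\t\tCIM\t5\t1\t9\t\t", sep = "\n")
  expect_error(read_qtl_file(bad), "unknown trait")
  expect_warning(skipped <- read_qtl_file(bad, unknown_traits = "skip"),
                 "XYZ")
  expect_equal(nrow(skipped), 0)

  swapped <- paste(header, "m1\tq1\tS1\tc3\tFS\t\t\tCIM\t5\t9\t1\t\t",
                   sep = "\n")
  expect_error(read_qtl_file(swapped), "ci_lo > ci_hi")
})

test_that("QTL files round-trip including missing fields", {
  spec <- synthetic_spec(n_chromosomes = 3, missing_position_frac = 0.2,
                         missing_ci_frac = 0.3)
  map <- generate_map(spec, seed = 5)
  recs <- generate_qtl_set(spec, map, seed = 5)$records
  path <- withr::local_tempfile(fileext = ".tsv")
  write_qtl_file(recs, path)
  back <- read_qtl_file(path)
  expect_equal(as.data.frame(back), as.data.frame(recs))
})

test_that("packaged tables load with consistent totals", {
  tabs <- cotton_tables()
  expect_equal(nrow(tabs$studies), 42)
  totals <- table_totals(tabs$trait_counts)
  expect_equal(sum(tabs$studies$n_qtl), totals$grand_total)
  expect_equal(totals$grand_total, 1223)
  # no fiber strength QTL on c17
  expect_equal(tabs$trait_counts$FS[tabs$trait_counts$chromosome == "c17"], 0)
  # every chromosome code in every fixture is one of c1..c26
  for (tab in tabs) {
    if ("chromosome" %in% names(tab)) {
      expect_true(all(tab$chromosome %in% chromosome_codes()))
    }
  }
  c11 <- tabs$clusters[tabs$clusters$name == "c11-cluster-1", ]
  expect_equal(c(c11$start_cM, c11$end_cM, c11$n_qtl), c(0, 20, 26))
  # per-chromosome tallies agree with the catalogues
  expect_equal(
    dplyr::count(tabs$clusters, chromosome)$n[order(
      as.integer(sub("c", "", dplyr::count(tabs$clusters, chromosome)$chromosome)))],
    tabs$tallies$n_clusters[tabs$tallies$n_clusters > 0])
})

test_that("trait vocabulary has 43 codes in 7 categories", {
  vocab <- trait_vocabulary()
  expect_equal(nrow(vocab), 43)
  expect_equal(anyDuplicated(vocab$trait), 0)
  expect_setequal(unique(vocab$category),
                  c("fiber quality", "yield", "seed quality", "morphological",
                    "resistance", "physiological", "drought tolerance"))
  expect_setequal(vocab$trait,
                  setdiff(names(cotton_trait_counts()), "chromosome"))
})
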