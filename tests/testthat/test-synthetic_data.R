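test_that("map generation is deterministic and respects bounds", {
  spec <- synthetic_spec(n_chromosomes = 26)
  m1 <- generate_map(spec, seed = 42)
  m2 <- generate_map(spec, seed = 42)
  expect_equal(m1, m2)
  expect_equal(unique(m1$chromosome), paste0("c", 1:26))
  lens <- map_lengths(m1)
  expect_true(all(lens$length_cM >= 80 - 5 & lens$length_cM <= 150))
  gaps <- m1$distance_from_previous_cM[m1$distance_from_previous_cM > 0]
  expect_true(all(gaps >= 1 & gaps <= 5))
  # first marker of each chromosome at 0
  first <- m1 %>% dplyr::group_by(chromosome) %>% dplyr::slice(1)
  expect_true(all(first$position_cM == 0))
})

test_that("generated collections are deterministic and track ground truth", {
  spec <- synthetic_spec(
    n_chromosomes = 3, length_range = c(100, 140), background_rate = 0.1,
    planted = tibble::tibble(chromosome = "c3", center_cM = 30, sd_cM = 2,
                             traits = "FS;FL;Micro", n_per_trait = 5))
  map <- generate_map(spec, seed = 7)
  g1 <- generate_qtl_set(spec, map, seed = 7)
  g2 <- generate_qtl_set(spec, map, seed = 7)
  expect_equal(g1, g2)
  # byte-identical emitted files under identical seeds
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_qtl_file(g1$records, f1); write_qtl_file(g2$records, f2)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  expect_equal(g1$truth$regions$n_qtl, 15L)
  expect_equal(nrow(g1$records), nrow(g1$truth$positions))
  # each planted QTL belongs to exactly one region
  planted_ids <- strsplit(g1$truth$regions$members, ";")[[1]]
  expect_equal(anyDuplicated(planted_ids), 0)
  expect_setequal(
    planted_ids,
    g1$truth$positions$qtl_name[g1$truth$positions$origin == "planted"])

  expect_error(
    generate_qtl_set(
      synthetic_spec(n_chromosomes = 1,
                     planted = tibble::tibble(chromosome = "c1",
                                              center_cM = 500, sd_cM = 1,
                                              traits = "FS",
                                              n_per_trait = 2)),
      map = generate_map(synthetic_spec(n_chromosomes = 1), 1), seed = 1),
    "off chromosome")
})

test_that("complete generated records project with zero exclusions", {
  for (seed in c(2, 12, 22)) {
    spec <- synthetic_spec(n_chromosomes = 4, background_rate = 0.3)
    map <- generate_map(spec, seed = seed)
    recs <- generate_qtl_set(spec, map, seed = seed)$records
    proj <- project_qtl(recs, map)
    expect_equal(nrow(proj$excluded), 0)
  }
})

test_that("records with all CIs blanked acquire them from flanking markers", {
  spec <- synthetic_spec(
    n_chromosomes = 2, background_rate = 0.2, missing_ci_frac = 1)
  map <- generate_map(spec, seed = 8)
  out <- generate_qtl_set(spec, map, seed = 8)
  expect_true(all(is.na(out$records$ci_lo_cM)))
  expect_true(all(!is.na(out$records$flank_left)))
  proj <- project_qtl(out$records, map)
  expect_equal(nrow(proj$excluded), 0)
  expect_true(all(!is.na(proj$kept$ci_lo_cM)))
  # flank-substituted CI brackets the position
  expect_true(all(proj$kept$ci_lo_cM <= proj$kept$position_cM &
                    proj$kept$position_cM <= proj$kept$ci_hi_cM))
})

test_that("a planted multi-trait region is recovered as a cluster", {
  spec <- synthetic_spec(
    n_chromosomes = 3, length_range = c(100, 140), background_rate = 0.02,
    planted = tibble::tibble(chromosome = "c3", center_cM = 30, sd_cM = 2,
                             traits = "FS;FL;Micro", n_per_trait = 5))
  map <- generate_map(spec, seed = 7)
  out <- generate_qtl_set(spec, map, seed = 7)
  proj <- project_qtl(out$records, map)
  cl <- detect_clusters(proj$kept)
  on_c3 <- cl[cl$chromosome == "c3", ]
  expect_gte(nrow(on_c3), 1)
  expect_true(any(on_c3$start_cM <= 30 & 30 <= on_c3$end_cM))
})

test_that("recovery report handles perfect and degenerate cases", {
  truth <- list(regions = tibble::tibble(
    region_id = c("region-1", "region-2"),
    chromosome = c("c1", "c2"), center_cM = c(20, 60)))
  calls <- tibble::tibble(chromosome = c("c1", "c2"),
                          start_cM = c(15, 55), end_cM = c(25, 65))
  perfect <- recovery_report(truth, calls)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$precision, 1)

  none <- recovery_report(truth, calls[0, ])
  expect_equal(none$recall, 0)
  expect_equal(none$precision, 0)
  expect_false(none$precision_defined)
})
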