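test_that("window scan matches hand-worked examples", {
  one <- scan_windows(c(1, 3, 5, 18), window = 20, min_count = 4)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end), c(1, 18))
  expect_equal(one$members[[1]], 1:4)

  expect_equal(nrow(scan_windows(c(1, 3, 5), window = 20, min_count = 4)), 0)
  expect_equal(nrow(scan_windows(numeric(0), 20, 4)), 0)

  two <- scan_windows(c(0, 2, 4, 6, 50, 52, 54, 56), window = 20,
                      min_count = 4)
  expect_equal(two$start, c(0, 50))
  expect_equal(two$end, c(6, 56))
})

test_that("window scan agrees with the brute-force oracle on random instances", {
  withr::with_seed(42, {
    for (i in 1:200) {
      n <- sample(0:12, 1)
      positions <- sort(round(runif(n, 0, 100), 2))
      window <- sample(c(5, 10, 20, 40), 1)
      min_count <- sample(2:5, 1)
      got <- scan_windows(positions, window, min_count)
      want <- brute_scan(positions, window, min_count)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$members, want$members)
    }
  })
})

test_that("clusters require several QTL of several traits in one window", {
  multi <- make_records("c3", c("FS", "FL", "Micro", "BW"), c(2, 8, 12, 18))
  cl <- detect_clusters(multi)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$name, "c3-cluster-1")
  expect_equal(cl$n_traits, 4L)

  mono <- make_records("c3", "Micro", c(2, 4, 6, 8, 10))
  expect_equal(nrow(detect_clusters(mono)), 0)  # "various traits" fails
  hs <- detect_hotspots(mono)
  expect_equal(nrow(hs), 1)  # but it is a hotspot
  expect_equal(hs$n_qtl, 5L)
  expect_equal(nrow(detect_clusters(mono, detection_config(min_traits = 1))), 1)
})

test_that("two planted groups far apart give two separate clusters", {
  recs <- make_records("c5", c("FS", "FL", "Micro", "VW"),
                       c(18, 20, 22, 24, 78, 80, 82, 84))
  cl <- detect_clusters(recs)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$name, c("c5-cluster-1", "c5-cluster-2"))
  expect_true(cl$start_cM[1] >= 18 && cl$end_cM[1] <= 24)
  expect_true(cl$start_cM[2] >= 78 && cl$end_cM[2] <= 84)
})

test_that("hotspots are single-trait aggregates at the count threshold", {
  recs <- dplyr::bind_rows(
    make_records("c2", "Micro", c(1, 5, 9, 14)),
    make_records("c2", "FS", 7))
  hs <- detect_hotspots(recs)
  expect_equal(nrow(hs), 1)
  expect_equal(hs$trait, "Micro")
  expect_equal(hs$n_qtl, 4L)

  few <- make_records("c2", "VW", c(1, 3, 5))
  expect_equal(nrow(detect_hotspots(few)), 0)
})

test_that("hotspot naming uses one genome-wide counter per trait", {
  recs <- dplyr::bind_rows(
    make_records("c16", "VW", c(0, 2, 4, 6)),
    make_records("c16", "VW", c(40, 42, 44, 46)),
    make_records("c16", "VW", c(80, 82, 84, 86)),
    make_records("c23", "VW", c(10, 12, 14, 16)),
    make_records("c23", "VW", c(60, 62, 64, 66)),
    make_records("c23", "FS", c(30, 32, 34, 36)))
  hs <- detect_hotspots(recs)
  vw <- hs[hs$trait == "VW", ]
  expect_equal(sort(vw$name),
               c("c16-VW-Hotspot-1", "c16-VW-Hotspot-2", "c16-VW-Hotspot-3",
                 "c23-VW-Hotspot-4", "c23-VW-Hotspot-5"))
  expect_equal(hs$name[hs$trait == "FS"], "c23-FS-Hotspot-1")
  # display labels follow the catalogue convention
  micro <- detect_hotspots(make_records("c3", "Micro", c(1, 3, 5, 7)))
  expect_equal(micro$name, "c3-Micronaire-Hotspot-1")
})

test_that("cluster numbering restarts per chromosome in start order", {
  recs <- dplyr::bind_rows(
    make_records("c5", c("FS", "FL"), c(1, 3, 5, 7)),
    make_records("c5", c("FS", "Micro"), c(40, 42, 44, 46)),
    make_records("c5", c("VW", "BW"), c(90, 92, 94, 96)),
    make_records("c6", c("FS", "FL"), c(10, 12, 14, 16)))
  cl <- detect_clusters(recs)
  expect_equal(cl$name,
               c("c5-cluster-1", "c5-cluster-2", "c5-cluster-3",
                 "c6-cluster-1"))
})

test_that("dense adjacent single-trait regions are recovered as hotspots", {
  # three VW aggregates shaped like the reference c16 intervals (0-23,
  # 30-50, 51-64 with 5, 7 and 4 QTL); the first is isolated and recovered
  # exactly, while the second and third sit one cM apart - closer than the
  # window - so the anchored-window merge reports them as one dense region
  recs <- make_records("c16", "VW",
                       c(0, 4, 8, 9, 23,
                         30, 41, 44, 46, 48, 49, 50,
                         51, 55, 60, 64))
  hs <- detect_hotspots(recs)
  expect_equal(nrow(hs), 2)
  expect_equal(c(hs$start_cM[1], hs$end_cM[1], hs$n_qtl[1]), c(0, 23, 5))
  expect_equal(c(hs$start_cM[2], hs$end_cM[2], hs$n_qtl[2]), c(30, 64, 11))
  expect_equal(sum(hs$n_qtl), 16L)
})

test_that("calls are invariant to input record order", {
  spec <- synthetic_spec(n_chromosomes = 3, background_rate = 0.3)
  map <- generate_map(spec, seed = 9)
  recs <- generate_qtl_set(spec, map, seed = 9)$records
  shuffled <- recs[withr::with_seed(1, sample(nrow(recs))), ]
  cfg <- detection_config(min_traits = 1)
  expect_equal(detect_clusters(recs, cfg), detect_clusters(shuffled, cfg))
  expect_equal(detect_hotspots(recs, cfg), detect_hotspots(shuffled, cfg))
})

test_that("every hotspot overlaps a trait-blind cluster on the same records", {
  cfg1 <- detection_config(min_traits = 1)
  n_hotspots_seen <- 0
  for (seed in 1:5) {
    spec <- synthetic_spec(n_chromosomes = 4, background_rate = 2,
                           background_traits = c("FS", "FL", "Micro"))
    map <- generate_map(spec, seed = seed)
    recs <- generate_qtl_set(spec, map, seed = seed)$records
    hs <- detect_hotspots(recs, cfg1)
    cl <- detect_clusters(recs, cfg1)
    n_hotspots_seen <- n_hotspots_seen + nrow(hs)
    for (i in seq_len(nrow(hs))) {
      same <- cl[cl$chromosome == hs$chromosome[i], ]
      expect_true(any(pmax(same$start_cM, hs$start_cM[i]) <=
                        pmin(same$end_cM, hs$end_cM[i])),
                  info = sprintf("seed %d hotspot %s", seed, hs$name[i]))
    }
  }
  expect_gt(n_hotspots_seen, 0)
})

test_that("ci-overlap membership can pull wide-CI QTL into a call", {
  recs <- make_records("c1", c("FS", "FL", "Micro", "BW"),
                       c(10, 12, 14, 40), ci_half = 2)
  # the 40 cM record has a CI reaching back into the dense window
  recs$ci_lo_cM[4] <- 12
  point <- detect_clusters(recs, detection_config(min_traits = 1))
  expect_equal(nrow(point), 0)  # only 3 points within 20 cM
  ci <- detect_clusters(recs, detection_config(min_traits = 1,
                                               membership = "ci-overlap"))
  expect_equal(nrow(ci), 1)
  expect_equal(ci$n_qtl, 4L)
})

test_that("false-positive rate has the right limits and monotonicity", {
  cfg <- detection_config(fpr_reps = 2000)
  expect_equal(estimate_false_positive_rate(3, 100, cfg), 0)
  big <- detection_config(window = 200, fpr_reps = 10)
  expect_equal(estimate_false_positive_rate(4, 100, big), 1)
  # deterministic given the seed
  expect_equal(estimate_false_positive_rate(8, 100, cfg),
               estimate_false_positive_rate(8, 100, cfg))
  # non-decreasing in window and n, non-increasing in min_cluster
  f <- function(n, w, m) estimate_false_positive_rate(
    n, 100, detection_config(window = w, min_cluster = m, fpr_reps = 4000))
  expect_lte(f(8, 10, 4), f(8, 20, 4))
  expect_lte(f(6, 20, 4), f(10, 20, 4))
  expect_gte(f(8, 20, 4), f(8, 20, 5))
})

test_that("false-positive rate matches an independent high-replicate estimate", {
  cfg <- detection_config(fpr_reps = 10000)
  est <- estimate_false_positive_rate(10, 100, cfg)
  # independent simulation with a different seed and more replicates
  oracle <- withr::with_seed(987654, {
    mean(vapply(1:40000, function(i) {
      x <- sort(runif(10, 0, 100))
      any(x[4:10] - x[1:7] <= 20)
    }, logical(1)))
  })
  se <- sqrt(est * (1 - est) / 10000 + oracle * (1 - oracle) / 40000)
  expect_lt(abs(est - oracle), 3 * se)
})
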