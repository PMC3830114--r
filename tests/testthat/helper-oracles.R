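# Independent brute-force window scanner: tests every interval between
# pairs of positions, keeps those with span <= window and >= min_count
# members, merges overlapping candidate intervals, reports member spans.
brute_scan <- function(positions, window, min_count) {
  n <- length(positions)
  empty <- tibble::tibble(start = numeric(), end = numeric(), members = list())
  if (n == 0) return(empty)
  cand <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (positions[j] - positions[i] <= window && (j - i + 1) >= min_count) {
        cand[[length(cand) + 1]] <- c(positions[i], positions[j])
      }
    }
  }
  if (length(cand) == 0) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  merged <- list(cand[1, ])
  for (k in seq_len(nrow(cand))[-1]) {
    cur <- merged[[length(merged)]]
    if (cand[k, 1] <= cur[2]) {
      merged[[length(merged)]] <- c(cur[1], max(cur[2], cand[k, 2]))
    } else {
      merged[[length(merged) + 1]] <- cand[k, ]
    }
  }
  purrr::map_dfr(merged, function(iv) {
    members <- which(positions >= iv[1] & positions <= iv[2])
    tibble::tibble(start = positions[members[1]],
                   end = positions[members[length(members)]],
                   members = list(members))
  })
}

# quick construction of projected QTL record tibbles for detection tests
make_records <- function(chromosome, trait, position, ci_half = 2,
                         study_id = "S01") {
  n <- length(position)
  tibble::tibble(
    map_name = "test",
    qtl_name = sprintf("q%03d", seq_len(n)),
    study_id = rep_len(study_id, n),
    chromosome = rep_len(chromosome, n),
    trait = rep_len(trait, n),
    lod = 3, r2 = 0.1, method = "CIM",
    position_cM = position,
    ci_lo_cM = pmax(position - ci_half, 0),
    ci_hi_cM = position + ci_half,
    flank_left = NA_character_, flank_right = NA_character_
  )
}

# two-chromosome toy map: c1 spans 0-100, c2 spans 0-120, markers every 10
make_map <- function() {
  txt <- paste0(
    "chromosome\tmarker\tdistance_from_previous_cM\n",
    paste(sprintf("c1\tA%02d\t%d", 0:10, c(0, rep(10, 10))), collapse = "\n"),
    "\n",
    paste(sprintf("c2\tB%02d\t%d", 0:12, c(0, rep(10, 12))), collapse = "\n")
  )
  read_map_file(txt)
}
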