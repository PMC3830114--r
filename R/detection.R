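#' Configuration for cluster and hotspot detection
#'
#' Detection declares a cluster or hotspot wherever enough QTL fall within a
#' sliding window of `window` cM (default 20, the region size within which
#' large aggregates of QTL are typically observed on the cotton consensus
#' map). Clusters require `min_cluster` QTL of at least `min_traits`
#' distinct trait types; hotspots require `min_hotspot` QTL of one single
#' trait.
#'
#' @param window Window width in cM (> 0).
#' @param min_cluster Minimum QTL per cluster (>= 2); default 4.
#' @param min_hotspot Minimum QTL per hotspot (>= 2); default 4, the
#'   smallest hotspot size in the reference catalogue.
#' @param min_traits Minimum distinct trait types per cluster (>= 1);
#'   default 2, implementing the "various traits" requirement.
#' @param membership `"point"` (a QTL belongs to a window if its point
#'   position falls inside) or `"ci-overlap"` (if its confidence interval
#'   intersects the window; wide-CI QTL may plausibly sit anywhere in their
#'   interval).
#' @param fpr_reps Monte-Carlo replicates for
#'   [estimate_false_positive_rate()].
#' @param seed Integer seed driving the Monte-Carlo estimator.
#' @return A `detection_config` list.
#' @export
detection_config <- function(window = 20, min_cluster = 4, min_hotspot = 4,
                             min_traits = 2,
                             membership = c("point", "ci-overlap"),
                             fpr_reps = 10000, seed = 20131111) {
  membership <- match.arg(membership)
  stopifnot(window > 0, min_cluster >= 2, min_hotspot >= 2, min_traits >= 1,
            fpr_reps >= 1)
  structure(list(window = window, min_cluster = min_cluster,
                 min_hotspot = min_hotspot, min_traits = min_traits,
                 membership = membership, fpr_reps = fpr_reps,
                 seed = as.integer(seed)),
            class = "detection_config")
}

#' Scan sorted positions for dense windows
#'
#' Candidate windows `[x_i, x_i + window]` are anchored at each position.
#' Windows holding at least `min_count` positions qualify; overlapping
#' qualifying windows are merged, and each merged region is reported as the
#' min-to-max span of its member positions. Anchoring windows at the
#' positions themselves (rather than on a grid) makes the calls
#' deterministic and invariant to input order; every position belongs to at
#' most one reported region.
#'
#' @param positions Numeric vector of positions in cM, sorted ascending.
#' @param window Window width in cM.
#' @param min_count Minimum number of positions per window.
#' @return A tibble with columns `start`, `end` and a list-column `members`
#'   of integer indices into `positions`. Zero rows when nothing qualifies.
#' @export
#' @examples
#' scan_windows(c(1, 3, 5, 18), window = 20, min_count = 4)
#' scan_windows(c(0, 2, 4, 6, 50, 52, 54, 56), window = 20, min_count = 4)
scan_windows <- function(positions, window, min_count) {
  n <- length(positions)
  empty <- tibble(start = numeric(), end = numeric(), members = list())
  if (n == 0) return(empty)
  if (is.unsorted(positions)) abort("`positions` must be sorted ascending")
  # index of the last position within each anchored window
  last_in <- findInterval(positions + window, positions)
  qualifies <- (last_in - seq_len(n) + 1) >= min_count
  if (!any(qualifies)) return(empty)
  anchors <- which(qualifies)
  # merge overlapping qualifying windows [x_a, x_a + window]
  runs <- list()
  run_start <- anchors[1]
  run_end_x <- positions[anchors[1]] + window
  for (a in anchors[-1]) {
    if (positions[a] <= run_end_x) {
      run_end_x <- max(run_end_x, positions[a] + window)
    } else {
      runs[[length(runs) + 1]] <- c(run_start, run_end_x)
      run_start <- a
      run_end_x <- positions[a] + window
    }
  }
  runs[[length(runs) + 1]] <- c(run_start, run_end_x)
  purrr::map_dfr(runs, function(r) {
    members <- which(positions >= positions[r[1]] & positions <= r[2])
    tibble(start = positions[members[1]],
           end = positions[members[length(members)]],
           members = list(members))
  })
}

# trait code -> the display label used in call names
hotspot_trait_label <- function(trait) {
  labels <- c(Micro = "Micronaire", LeafMorph = "Leaf", Color = "color")
  out <- unname(labels[trait])
  ifelse(is.na(out), trait, out)
}

chrom_number <- function(chromosome) {
  as.integer(sub("^c", "", chromosome))
}

sort_records <- function(records) {
  records[order(chrom_number(records$chromosome), records$position_cM,
                records$qtl_name), , drop = FALSE]
}

# scan one chromosome's records; membership either by point position or by
# CI overlap with the candidate windows
call_regions <- function(records, window, min_count, membership) {
  recs <- records[order(records$position_cM, records$qtl_name), , drop = FALSE]
  if (membership == "point") {
    hits <- scan_windows(recs$position_cM, window, min_count)
  } else {
    hits <- scan_windows_ci(recs$position_cM, recs$ci_lo_cM, recs$ci_hi_cM,
                            window, min_count)
  }
  hits$records <- lapply(hits$members, function(idx) recs[idx, , drop = FALSE])
  hits
}

# ci-overlap variant of scan_windows: a record belongs to a candidate
# window [x_i, x_i + w] when its CI intersects it; qualifying overlapping
# windows merge, and each record is assigned to the single merged region
# its CI overlaps most (ties toward the leftmost region)
scan_windows_ci <- function(positions, ci_lo, ci_hi, window, min_count) {
  n <- length(positions)
  empty <- tibble(start = numeric(), end = numeric(), members = list())
  if (n == 0) return(empty)
  counts <- vapply(seq_len(n), function(i) {
    sum(ci_lo <= positions[i] + window & ci_hi >= positions[i])
  }, integer(1))
  anchors <- which(counts >= min_count)
  if (length(anchors) == 0) return(empty)
  runs <- list()
  run_lo <- positions[anchors[1]]
  run_hi <- positions[anchors[1]] + window
  for (a in anchors[-1]) {
    if (positions[a] <= run_hi) {
      run_hi <- max(run_hi, positions[a] + window)
    } else {
      runs[[length(runs) + 1]] <- c(run_lo, run_hi)
      run_lo <- positions[a]
      run_hi <- positions[a] + window
    }
  }
  runs[[length(runs) + 1]] <- c(run_lo, run_hi)
  lo <- vapply(runs, `[`, numeric(1), 1)
  hi <- vapply(runs, `[`, numeric(1), 2)
  assignment <- vapply(seq_len(n), function(i) {
    ov <- pmin(ci_hi[i], hi) - pmax(ci_lo[i], lo)
    if (all(ov < 0)) return(NA_integer_)
    which.max(ov)
  }, integer(1))
  out <- purrr::map_dfr(seq_along(runs), function(k) {
    members <- which(!is.na(assignment) & assignment == k)
    if (length(members) < min_count) return(NULL)
    tibble(start = min(positions[members]), end = max(positions[members]),
           members = list(members))
  })
  if (nrow(out) == 0) empty else out
}

#' Detect multi-trait QTL clusters
#'
#' Scans each chromosome's projected QTL (all trait types jointly) with
#' [scan_windows()] and keeps regions holding at least
#' `config$min_cluster` QTL of at least `config$min_traits` distinct
#' traits. Clusters are numbered from 1 per chromosome in start order and
#' named `c{N}-cluster-{i}`.
#'
#' @param records Tibble of kept (projected) QTL records.
#' @param config A [detection_config()].
#' @return A tibble of cluster calls: `name`, `chromosome`, `start_cM`,
#'   `end_cM`, `n_qtl`, `n_traits`, `members` (semicolon-joined QTL names).
#' @export
detect_clusters <- function(records, config = detection_config()) {
  records <- sort_records(records)
  out <- purrr::map_dfr(split_by_chrom(records), function(recs) {
    hits <- call_regions(recs, config$window, config$min_cluster,
                         config$membership)
    if (nrow(hits) == 0) return(NULL)
    hits$n_traits <- vapply(hits$records,
                            function(r) length(unique(r$trait)), integer(1))
    hits <- hits[hits$n_traits >= config$min_traits, , drop = FALSE]
    if (nrow(hits) == 0) return(NULL)
    tibble(
      chromosome = recs$chromosome[1],
      start_cM = hits$start, end_cM = hits$end,
      n_qtl = vapply(hits$records, nrow, integer(1)),
      n_traits = hits$n_traits,
      members = vapply(hits$records,
                       function(r) paste(r$qtl_name, collapse = ";"),
                       character(1))
    )
  })
  if (nrow(out) == 0) {
    return(tibble(name = character(), chromosome = character(),
                  start_cM = numeric(), end_cM = numeric(),
                  n_qtl = integer(), n_traits = integer(),
                  members = character()))
  }
  out <- out[order(chrom_number(out$chromosome), out$start_cM), , drop = FALSE]
  out <- out %>%
    group_by(.data$chromosome) %>%
    mutate(name = sprintf("%s-cluster-%d", .data$chromosome, row_number())) %>%
    ungroup()
  out[, c("name", "chromosome", "start_cM", "end_cM", "n_qtl", "n_traits",
          "members")]
}

#' Detect single-trait QTL hotspots
#'
#' Scans each chromosome separately per trait and keeps regions holding at
#' least `config$min_hotspot` QTL of that one trait. Hotspots are named
#' `c{N}-{Trait}-Hotspot-{j}` where `j` is a single genome-wide counter per
#' trait, incremented in chromosome order then start order (so e.g. the
#' fifth VW hotspot genome-wide is `...-Hotspot-5` regardless of its
#' chromosome).
#'
#' @inheritParams detect_clusters
#' @return A tibble of hotspot calls: `name`, `chromosome`, `trait`,
#'   `start_cM`, `end_cM`, `n_qtl`, `members`.
#' @export
detect_hotspots <- function(records, config = detection_config()) {
  records <- sort_records(records)
  out <- purrr::map_dfr(
    split(records, records$trait),
    function(trecs) {
      purrr::map_dfr(split_by_chrom(trecs), function(recs) {
        hits <- call_regions(recs, config$window, config$min_hotspot,
                             config$membership)
        if (nrow(hits) == 0) return(NULL)
        tibble(
          chromosome = recs$chromosome[1],
          trait = recs$trait[1],
          start_cM = hits$start, end_cM = hits$end,
          n_qtl = vapply(hits$records, nrow, integer(1)),
          members = vapply(hits$records,
                           function(r) paste(r$qtl_name, collapse = ";"),
                           character(1))
        )
      })
    })
  if (nrow(out) == 0) {
    return(tibble(name = character(), chromosome = character(),
                  trait = character(), start_cM = numeric(),
                  end_cM = numeric(), n_qtl = integer(),
                  members = character()))
  }
  out <- out[order(out$trait, chrom_number(out$chromosome), out$start_cM), ,
             drop = FALSE]
  out <- out %>%
    group_by(.data$trait) %>%
    mutate(name = sprintf("%s-%s-Hotspot-%d", .data$chromosome,
                          hotspot_trait_label(.data$trait), row_number())) %>%
    ungroup()
  out <- out[order(chrom_number(out$chromosome), out$start_cM, out$trait), ,
             drop = FALSE]
  out[, c("name", "chromosome", "trait", "start_cM", "end_cM", "n_qtl",
          "members")]
}

split_by_chrom <- function(records) {
  split(records, factor(records$chromosome,
                        levels = unique(records$chromosome)))
}

#' Monte-Carlo false-positive rate of cluster detection
#'
#' Estimates the probability that `n_qtl` QTL placed uniformly at random on
#' a chromosome of `chrom_length` cM produce at least one cluster call at
#' the configured window and `min_cluster` threshold (trait labels are
#' ignored; this is the trait-blind density null). The estimate is the hit
#' fraction over `config$fpr_reps` replicates and is deterministic given
#' `config$seed`.
#'
#' @param n_qtl Number of QTL placed (>= 0).
#' @param chrom_length Chromosome length in cM (> 0).
#' @param config A [detection_config()].
#' @return A single probability.
#' @export
estimate_false_positive_rate <- function(n_qtl, chrom_length,
                                         config = detection_config()) {
  stopifnot(n_qtl >= 0, chrom_length > 0)
  m <- config$min_cluster
  if (n_qtl < m) return(0)
  if (config$window >= chrom_length) return(1)
  withr::with_seed(config$seed, {
    hits <- vapply(seq_len(config$fpr_reps), function(rep) {
      x <- sort(runif(n_qtl, 0, chrom_length))
      any(x[m:n_qtl] - x[1:(n_qtl - m + 1)] <= config$window)
    }, logical(1))
    mean(hits)
  })
}
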