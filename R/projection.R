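#' Resolve QTL positions and confidence intervals against a consensus map
#'
#' Applies the placement and CI-substitution rules used when pooling QTL
#' from heterogeneous studies onto one consensus map:
#'
#' * a record with an explicit position and CI is returned unchanged;
#' * a missing position is replaced by the midpoint of the two flanking
#'   marker positions on the record's chromosome;
#' * a missing CI is replaced by the flanking marker positions themselves.
#'
#' Records that cannot be resolved are flagged rather than silently dropped:
#' `MARKER_NOT_ON_MAP` when a named flanking marker is absent from the map
#' (on that chromosome), `UNRESOLVABLE` when neither a position+CI nor both
#' flanking markers are available.
#'
#' @param records Tibble of QTL records, see [read_qtl_file()].
#' @param map A `consensus_map`, see [read_map_file()].
#' @return The records tibble with `position_cM`, `ci_lo_cM`, `ci_hi_cM`
#'   filled where possible, plus a character column `.reason` (`NA` when the
#'   record resolved cleanly).
#' @export
place_qtl <- function(records, map) {
  marker_pos <- function(chrom, marker) {
    idx <- match(paste(chrom, marker), paste(map$chromosome, map$marker))
    map$position_cM[idx]
  }
  lpos <- marker_pos(records$chromosome, records$flank_left)
  rpos <- marker_pos(records$chromosome, records$flank_right)
  has_flanks_named <- !is.na(records$flank_left) & !is.na(records$flank_right)
  flanks_on_map <- has_flanks_named & !is.na(lpos) & !is.na(rpos)
  flo <- pmin(lpos, rpos)
  fhi <- pmax(lpos, rpos)

  out <- records
  reason <- rep(NA_character_, nrow(records))

  need_pos <- is.na(out$position_cM)
  need_ci <- is.na(out$ci_lo_cM) | is.na(out$ci_hi_cM)
  needs_flanks <- need_pos | need_ci

  # flanks named but not locatable on this chromosome of the map
  bad_marker <- needs_flanks & has_flanks_named & !flanks_on_map
  reason[bad_marker] <- "MARKER_NOT_ON_MAP"
  # nothing to resolve from at all
  unresolvable <- needs_flanks & !has_flanks_named
  reason[unresolvable] <- "UNRESOLVABLE"

  fill <- needs_flanks & flanks_on_map
  fill_pos <- fill & need_pos
  out$position_cM[fill_pos] <- (flo[fill_pos] + fhi[fill_pos]) / 2
  fill_ci <- fill & need_ci
  out$ci_lo_cM[fill_ci] <- flo[fill_ci]
  out$ci_hi_cM[fill_ci] <- fhi[fill_ci]
  # a substituted position must be covered by the CI: widen minimally
  widen <- fill & !is.na(out$position_cM) & !is.na(out$ci_lo_cM) &
    !is.na(out$ci_hi_cM)
  out$ci_lo_cM[widen] <- pmin(out$ci_lo_cM[widen], out$position_cM[widen])
  out$ci_hi_cM[widen] <- pmax(out$ci_hi_cM[widen], out$position_cM[widen])

  out$.reason <- reason
  out
}

#' Project QTL records onto a consensus map with exclusion rules
#'
#' Runs [place_qtl()] and then applies the exclusion rules of the pooled
#' analysis: records whose resolved position falls outside the chromosome
#' span of the consensus map are excluded as `OUT_OF_RANGE`, and a QTL name
#' reported at two or more distinct positions on one chromosome within one
#' study is excluded entirely (all copies) as `MULTI_LOCATION`. Exclusions
#' are reported, never raised as errors.
#'
#' The result partitions the input: every input record lands in `kept` or in
#' `excluded` with a reason code from `{MARKER_NOT_ON_MAP, MULTI_LOCATION,
#' OUT_OF_RANGE, UNRESOLVABLE}`. Every kept record has a position and CI
#' with `ci_lo <= position <= ci_hi` and `0 <= position <= ` chromosome
#' length. Projection is idempotent: re-projecting the kept set excludes
#' nothing.
#'
#' @param records Tibble of QTL records.
#' @param map A `consensus_map`.
#' @param verbose Emit one message per excluded record.
#' @return An object of class `qtl_projection`: a list with tibbles `kept`
#'   and `excluded` (the latter with a `reason` column). Use [tidy()] for a
#'   single annotated tibble and [glance()] for counts.
#' @export
project_qtl <- function(records, map, verbose = FALSE) {
  stopifnot(inherits(map, "consensus_map"))
  missing_chrom <- setdiff(unique(records$chromosome), unique(map$chromosome))
  if (length(missing_chrom) > 0) {
    abort(paste0("chromosome(s) absent from the consensus map: ",
                 paste(missing_chrom, collapse = ", ")))
  }
  placed <- place_qtl(records, map)
  lengths <- map_lengths(map)
  placed <- placed %>%
    left_join(lengths[, c("chromosome", "length_cM")], by = "chromosome")

  oor <- is.na(placed$.reason) &
    (placed$position_cM < 0 | placed$position_cM > placed$length_cM)
  placed$.reason[oor] <- "OUT_OF_RANGE"

  # one qtl_name at >= 2 distinct positions on one chromosome in one study
  multi <- placed %>%
    filter(is.na(.data$.reason)) %>%
    group_by(.data$study_id, .data$chromosome, .data$qtl_name) %>%
    summarise(n_pos = dplyr::n_distinct(.data$position_cM), .groups = "drop") %>%
    filter(.data$n_pos >= 2)
  if (nrow(multi) > 0) {
    is_multi <- paste(placed$study_id, placed$chromosome, placed$qtl_name) %in%
      paste(multi$study_id, multi$chromosome, multi$qtl_name)
    placed$.reason[is_multi & is.na(placed$.reason)] <- "MULTI_LOCATION"
  }

  placed$length_cM <- NULL
  kept <- placed %>% filter(is.na(.data$.reason)) %>% select(-".reason")
  excluded <- placed %>%
    filter(!is.na(.data$.reason)) %>%
    rename(reason = ".reason")
  if (verbose) {
    for (i in seq_len(nrow(excluded))) {
      inform(sprintf("excluded %s (%s, %s): %s",
                     excluded$qtl_name[i], excluded$study_id[i],
                     excluded$chromosome[i], excluded$reason[i]))
    }
  }
  structure(list(kept = kept, excluded = excluded, n_input = nrow(records)),
            class = "qtl_projection")
}

#' @export
print.qtl_projection <- function(x, ...) {
  cat(sprintf("<qtl_projection> %d record(s): %d kept, %d excluded\n",
              x$n_input, nrow(x$kept), nrow(x$excluded)))
  if (nrow(x$excluded) > 0) {
    tab <- table(x$excluded$reason)
    cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @describeIn project_qtl One tibble of all records with a `status`
#'   (`kept`/`excluded`) and `reason` column.
#' @param x A `qtl_projection` object.
#' @param ... Unused.
#' @method tidy qtl_projection
#' @export
tidy.qtl_projection <- function(x, ...) {
  bind_rows(
    x$kept %>% mutate(status = "kept", reason = NA_character_),
    x$excluded %>% mutate(status = "excluded")
  )
}

#' @describeIn project_qtl One-row summary of record counts.
#' @method glance qtl_projection
#' @export
glance.qtl_projection <- function(x, ...) {
  tibble(
    n_input = x$n_input,
    n_kept = nrow(x$kept),
    n_excluded = nrow(x$excluded)
  )
}

#' Write the exclusion report of a projection as TSV
#'
#' @param projection A `qtl_projection`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_exclusion_report <- function(projection, file) {
  readr::write_tsv(
    projection$excluded[, c("qtl_name", "study_id", "chromosome", "reason")],
    file)
  invisible(file)
}

#' Convert a positional confidence interval to a standard deviation
#'
#' Bridges reported QTL confidence intervals to the per-QTL standard
#' deviations used by the mixture meta-model: assuming the CI is a
#' symmetric normal interval at confidence `level`, `sigma = (ci_hi - ci_lo)
#' / (2 * z)` with `z` the standard-normal quantile of `(1 + level) / 2`.
#' The result is floored at 0.1 cM so that degenerate (zero-width) CIs do
#' not produce zero-variance mixture components.
#'
#' @param ci_lo,ci_hi CI bounds in cM (vectorized).
#' @param level Confidence level in (0, 1); default 0.95.
#' @param floor_cm Lower bound on the returned sigma, in cM.
#' @return Numeric vector of standard deviations in cM.
#' @export
#' @examples
#' ci_to_sigma(10, 20)        # ~2.551 cM
#' ci_to_sigma(0, 39.2)       # ~10 cM
#' ci_to_sigma(5, 5)          # floored at 0.1 cM
ci_to_sigma <- function(ci_lo, ci_hi, level = 0.95, floor_cm = 0.1) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    abort("`level` must be a single number strictly between 0 and 1")
  }
  if (any(ci_hi < ci_lo, na.rm = TRUE)) {
    abort("ci_hi must be >= ci_lo")
  }
  z <- qnorm((1 + level) / 2)
  pmax((ci_hi - ci_lo) / (2 * z), floor_cm)
}
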