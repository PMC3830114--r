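#' Read a consensus linkage map file
#'
#' Map files are UTF-8, tab-separated with one header line; lines starting
#' with `#` are ignored. Each row gives a marker and its genetic distance in
#' centimorgans (cM) from the previous marker on the same chromosome; the
#' first marker of a chromosome must have distance 0. Cumulative positions
#' are computed as the running sum of the distances, so a chromosome's
#' length is the position of its last marker.
#'
#' Expected columns: `chromosome`, `marker`, `distance_from_previous_cM`.
#'
#' @param file Path to a map file, or a literal string containing the file
#'   content (detected by the presence of a newline).
#' @param chromosomes Allowed chromosome codes; defaults to
#'   [chromosome_codes()].
#' @return A `consensus_map` tibble with columns `chromosome`, `marker`,
#'   `distance_from_previous_cM` and the derived `position_cM`.
#' @export
#' @examples
#' txt <- "chromosome\tmarker\tdistance_from_previous_cM
#' c1\tM1\t0
#' c1\tM2\t5.2
#' c1\tM3\t3.1"
#' read_map_file(txt)
read_map_file <- function(file, chromosomes = chromosome_codes()) {
  raw <- read_tsv_flex(file, cols = c("chromosome", "marker",
                                      "distance_from_previous_cM"))
  raw$distance_from_previous_cM <- as.numeric(raw$distance_from_previous_cM)
  bad <- which(is.na(raw$distance_from_previous_cM) |
                 raw$distance_from_previous_cM < 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "map format error: negative or missing distance at data line %d (marker '%s')",
      bad[1], raw$marker[bad[1]]))
  }
  unknown <- setdiff(unique(raw$chromosome), chromosomes)
  if (length(unknown) > 0) {
    abort(paste0("map format error: unknown chromosome code(s): ",
                 paste(unknown, collapse = ", ")))
  }
  dup <- raw %>%
    count(.data$chromosome, .data$marker) %>%
    filter(n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "map format error: duplicate marker '%s' on chromosome %s",
      dup$marker[1], dup$chromosome[1]))
  }
  map <- raw %>%
    group_by(.data$chromosome) %>%
    mutate(position_cM = cumsum(.data$distance_from_previous_cM)) %>%
    ungroup()
  first <- map %>% group_by(.data$chromosome) %>% dplyr::slice(1) %>% ungroup()
  if (any(first$distance_from_previous_cM != 0)) {
    bad_chrom <- first$chromosome[first$distance_from_previous_cM != 0][1]
    abort(sprintf(
      "map format error: first marker on chromosome %s must have distance 0",
      bad_chrom))
  }
  new_consensus_map(map)
}

new_consensus_map <- function(x) {
  class(x) <- c("consensus_map", class(x))
  x
}

#' @export
print.consensus_map <- function(x, ...) {
  len <- map_lengths(x)
  cat(sprintf("<consensus_map> %d markers on %d chromosome(s), total span %.1f cM\n",
              nrow(x), nrow(len), sum(len$length_cM)))
  NextMethod()
}

#' Per-chromosome lengths of a consensus map
#'
#' @param map A `consensus_map`, see [read_map_file()].
#' @return A tibble with columns `chromosome`, `length_cM` (position of the
#'   last marker) and `n_markers`.
#' @export
map_lengths <- function(map) {
  map %>%
    group_by(.data$chromosome) %>%
    summarise(length_cM = max(.data$position_cM), n_markers = n(),
              .groups = "drop")
}

#' Write a consensus map file
#'
#' Inverse of [read_map_file()]: writes the tab-separated map format so that
#' reading the file back reproduces the map.
#'
#' @param map A `consensus_map` tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_map_file <- function(map, file) {
  readr::write_tsv(
    map[, c("chromosome", "marker", "distance_from_previous_cM")], file)
  invisible(file)
}

qtl_file_columns <- function() {
  c("map_name", "qtl_name", "study_id", "chromosome", "trait", "lod", "r2",
    "method", "position_cM", "ci_lo_cM", "ci_hi_cM", "flank_left",
    "flank_right")
}

#' Read a QTL description file
#'
#' QTL files are UTF-8, tab-separated with one header line; `#` comment
#' lines are ignored. Each row describes one QTL reported by a source study:
#' its name, study provenance, chromosome, trait code, LOD score, phenotypic
#' variance explained (R^2), mapping method, map position and confidence
#' interval (CI) in cM, and optional flanking marker names. Numeric fields
#' may be empty; they are stored as missing (`NA`), never as zero, and are
#' resolved later by projection against the consensus map (see
#' [place_qtl()]).
#'
#' R^2 values are kept exactly as declared by each study (no percent/fraction
#' normalization); LOD and R^2 are carried through reports but play no role
#' in QTL placement.
#'
#' @param file Path to a QTL file, or a literal string of its content.
#' @param vocabulary Trait vocabulary, see [trait_vocabulary()]. Trait labels
#'   are normalized to canonical codes via [normalize_traits()].
#' @param unknown_traits `"error"` (default) to fail on a trait label outside
#'   the vocabulary, or `"skip"` to drop such records with a warning.
#' @return A tibble of QTL records with the columns of the file format.
#' @export
read_qtl_file <- function(file, vocabulary = trait_vocabulary(),
                          unknown_traits = c("error", "skip")) {
  unknown_traits <- match.arg(unknown_traits)
  raw <- read_tsv_flex(file, cols = qtl_file_columns())
  for (col in c("lod", "r2", "position_cM", "ci_lo_cM", "ci_hi_cM")) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  for (col in c("flank_left", "flank_right", "method", "map_name")) {
    raw[[col]][!is.na(raw[[col]]) & raw[[col]] == ""] <- NA_character_
  }
  unknown_chrom <- setdiff(unique(raw$chromosome), chromosome_codes())
  if (length(unknown_chrom) > 0) {
    abort(paste0("QTL format error: unknown chromosome code(s): ",
                 paste(unknown_chrom, collapse = ", ")))
  }
  canon <- normalize_traits(raw$trait, vocabulary)
  if (anyNA(canon)) {
    offending <- unique(raw$trait[is.na(canon)])
    msg <- paste0("unknown trait code(s): ", paste(offending, collapse = ", "))
    if (unknown_traits == "error") {
      abort(paste0("QTL format error: ", msg))
    }
    warn(paste0(msg, "; ", sum(is.na(canon)), " record(s) skipped"))
    raw <- raw[!is.na(canon), , drop = FALSE]
    canon <- canon[!is.na(canon)]
  }
  raw$trait <- canon
  bad_ci <- which(!is.na(raw$ci_lo_cM) & !is.na(raw$ci_hi_cM) &
                    raw$ci_lo_cM > raw$ci_hi_cM)
  if (length(bad_ci) > 0) {
    abort(sprintf(
      "QTL format error: ci_lo > ci_hi for QTL '%s'", raw$qtl_name[bad_ci[1]]))
  }
  out_ci <- which(!is.na(raw$position_cM) & !is.na(raw$ci_lo_cM) &
                    !is.na(raw$ci_hi_cM) &
                    (raw$position_cM < raw$ci_lo_cM |
                       raw$position_cM > raw$ci_hi_cM))
  if (length(out_ci) > 0) {
    abort(sprintf(
      "QTL format error: position outside its confidence interval for QTL '%s'",
      raw$qtl_name[out_ci[1]]))
  }
  as_tibble(raw)
}

#' Write a QTL description file
#'
#' Inverse of [read_qtl_file()]. Missing numeric fields are written as empty
#' strings, preserving the absent-not-zero convention.
#'
#' @param records Tibble of QTL records.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_qtl_file <- function(records, file) {
  readr::write_tsv(records[, qtl_file_columns()], file, na = "")
  invisible(file)
}

# read a TSV from a path or from literal text; '#' comments dropped
read_tsv_flex <- function(file, cols) {
  if (length(file) == 1 && grepl("\n", file)) file <- I(file)
  out <- readr::read_tsv(file, comment = "#", col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    na = character())
  missing_cols <- setdiff(cols, names(out))
  if (length(missing_cols) > 0) {
    abort(paste0("format error: missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out[, cols]
}

## ---- packaged reference tables ------------------------------------------

fixture_path <- function(name) {
  path <- system.file("extdata", name, package = "cottonqtl")
  if (path == "") abort(sprintf("fixture '%s' not found", name))
  path
}

read_fixture <- function(name, col_types) {
  readr::read_tsv(fixture_path(name), col_types = col_types, progress = FALSE)
}

#' Packaged study list (42 source QTL studies)
#'
#' One row per source publication contributing QTL to the cotton meta-QTL
#' reference analysis: author, journal, year, number of QTL used, mapping
#' population type and broad trait type.
#'
#' @return A tibble with 42 rows.
#' @export
cotton_studies <- function() {
  out <- read_fixture("table1_studies.tsv", "cciicc")
  if (nrow(out) != 42 || any(out$n_qtl < 1) || sum(out$n_qtl) != 1223) {
    abort("fixture 'table1_studies.tsv' is corrupted")
  }
  out
}

#' Packaged trait-by-chromosome QTL count matrix
#'
#' The reference distribution of 1,223 QTL over the 26 cotton chromosomes
#' and 43 trait codes, in wide form (one row per chromosome, one column per
#' trait code).
#'
#' @return A 26 x 44 tibble (`chromosome` plus 43 trait count columns).
#' @export
cotton_trait_counts <- function() {
  out <- read_fixture("table2_trait_counts.tsv",
                      readr::cols(chromosome = "c", .default = "i"))
  vocab <- trait_vocabulary()
  ok <- nrow(out) == 26 &&
    setequal(setdiff(names(out), "chromosome"), vocab$trait) &&
    all(out$chromosome == chromosome_codes()) &&
    !anyNA(out) && all(as.matrix(out[-1]) >= 0) &&
    sum(out[-1]) == 1223
  if (!ok) abort("fixture 'table2_trait_counts.tsv' is corrupted")
  out[, c("chromosome", vocab$trait)]
}

#' Packaged QTL cluster catalogue
#'
#' The reference catalogue of 76 multi-trait QTL clusters: name
#' (`c{N}-cluster-{i}`), chromosome, approximate interval in cM and number
#' of member QTL.
#'
#' @return A tibble with 76 rows.
#' @export
cotton_cluster_catalogue <- function() {
  out <- read_fixture("table3_clusters.tsv", "ccddi")
  ok <- nrow(out) == 76 && all(out$start_cM <= out$end_cM) &&
    all(out$n_qtl >= 4) && all(out$chromosome %in% chromosome_codes())
  if (!ok) abort("fixture 'table3_clusters.tsv' is corrupted")
  out
}

#' Packaged QTL hotspot catalogue
#'
#' The reference catalogue of 51 single-trait QTL hotspots: name
#' (`c{N}-{Trait}-Hotspot-{j}`), chromosome, trait code, interval in cM and
#' number of member QTL.
#'
#' @return A tibble with 51 rows.
#' @export
cotton_hotspot_catalogue <- function() {
  out <- read_fixture("table3_hotspots.tsv", "cccddi")
  ok <- nrow(out) == 51 && all(out$start_cM <= out$end_cM) &&
    all(out$n_qtl >= 4) &&
    all(out$trait %in% trait_vocabulary()$trait)
  if (!ok) abort("fixture 'table3_hotspots.tsv' is corrupted")
  out
}

#' Packaged per-chromosome cluster/hotspot tallies
#'
#' Number of clusters and hotspots on each of the 26 chromosomes in the
#' reference catalogue.
#'
#' @return A tibble with 26 rows and columns `chromosome`, `n_clusters`,
#'   `n_hotspots`.
#' @export
cotton_call_tallies <- function() {
  out <- read_fixture("table4_tallies.tsv", "cii")
  ok <- nrow(out) == 26 && sum(out$n_clusters) == 76 &&
    sum(out$n_hotspots) == 51
  if (!ok) abort("fixture 'table4_tallies.tsv' is corrupted")
  out
}

#' Load all packaged reference tables at once
#'
#' @return A named list with elements `studies`, `trait_counts`, `clusters`,
#'   `hotspots` and `tallies`.
#' @export
cotton_tables <- function() {
  list(
    studies = cotton_studies(),
    trait_counts = cotton_trait_counts(),
    clusters = cotton_cluster_catalogue(),
    hotspots = cotton_hotspot_catalogue(),
    tallies = cotton_call_tallies()
  )
}
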