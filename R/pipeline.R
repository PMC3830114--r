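#' Configuration for the end-to-end meta-QTL pipeline
#'
#' @param map_file Path to the consensus map file.
#' @param qtl_file Path to the QTL description file.
#' @param out_dir Output directory (created if absent).
#' @param detection A [detection_config()].
#' @param meta A [meta_model_config()].
#' @param alpha Significance level for the distribution tests.
#' @param overlap_cm Homoeolog comparison slack in cM.
#' @param verbose Log one line per stage and per exclusion.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(map_file, qtl_file, out_dir,
                            detection = detection_config(),
                            meta = meta_model_config(),
                            alpha = 0.05, overlap_cm = 10, verbose = TRUE) {
  if (!file.exists(map_file)) abort(paste0("map file not found: ", map_file))
  if (!file.exists(qtl_file)) abort(paste0("QTL file not found: ", qtl_file))
  structure(list(map_file = map_file, qtl_file = qtl_file, out_dir = out_dir,
                 detection = detection, meta = meta, alpha = alpha,
                 overlap_cm = overlap_cm, verbose = verbose),
            class = "pipeline_config")
}

stage_msg <- function(verbose, fmt, ...) {
  if (verbose) inform(sprintf(paste0("[cottonqtl] ", fmt), ...))
}

#' Run the full meta-QTL pipeline
#'
#' Orchestrates project -> detect -> meta-model -> genome statistics over
#' one map/QTL input pair and writes all reports to `config$out_dir`:
#' exclusion report, cluster and hotspot calls, per-chromosome meta-QTL
#' intervals, the trait-by-chromosome tabulation, chi-square tests,
#' homoeolog comparison and a YAML run manifest. Identical configuration
#' and inputs produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A `qtl_pipeline` list with elements `manifest`, `projection`,
#'   `clusters`, `hotspots`, `metaqtl`, `trait_table`, `tests`,
#'   `homoeologs` and `files`, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  v <- config$verbose
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
  }

  map <- run_stage("read_map", read_map_file(config$map_file))
  stage_msg(v, "read map: %d markers, %d chromosome(s)", nrow(map),
            nrow(map_lengths(map)))
  records <- run_stage("read_qtl", read_qtl_file(config$qtl_file))
  stage_msg(v, "read QTL: %d record(s)", nrow(records))

  projection <- run_stage("project", project_qtl(records, map, verbose = v))
  stage_msg(v, "projection: %d kept, %d excluded", nrow(projection$kept),
            nrow(projection$excluded))

  clusters <- run_stage("detect",
                        detect_clusters(projection$kept, config$detection))
  hotspots <- run_stage("detect",
                        detect_hotspots(projection$kept, config$detection))
  stage_msg(v, "detection: %d cluster(s), %d hotspot(s)", nrow(clusters),
            nrow(hotspots))

  lengths <- map_lengths(map)
  metaqtl <- run_stage("meta", purrr::map_dfr(
    split_by_chrom(sort_records(projection$kept)),
    function(recs) {
      chrom <- recs$chromosome[1]
      sel <- select_model(recs$position_cM,
                          ci_to_sigma(recs$ci_lo_cM, recs$ci_hi_cM),
                          config$meta)
      if (!sel$best$converged) {
        warn(sprintf("EM hit max_iter on chromosome %s", chrom))
      }
      iv <- metaqtl_intervals(
        sel$best, lengths$length_cM[lengths$chromosome == chrom])
      mutate(iv, chromosome = chrom, K = sel$best$K, .before = 1)
    }))
  stage_msg(v, "meta-model: %d meta-QTL over %d chromosome(s)",
            nrow(metaqtl), length(unique(metaqtl$chromosome)))

  trait_table <- run_stage("stats", tabulate_qtl(projection$kept))
  totals <- table_totals(trait_table)
  # uniformity is tested over the chromosomes the map actually covers
  present <- totals$row_totals$chromosome %in% lengths$chromosome
  uniformity <- if (sum(present) >= 2) {
    run_stage("stats", uniformity_chisq(totals$row_totals$total[present],
                                        alpha = config$alpha))
  } else {
    NULL
  }
  subgenome <- run_stage("stats", subgenome_counts(trait_table,
                                                   alpha = config$alpha))
  homoeologs <- run_stage("stats", compare_homoeologs(
    bind_rows(clusters %>% mutate(trait = NA_character_), hotspots),
    overlap_cm = config$overlap_cm))
  tests <- bind_rows(
    if (!is.null(uniformity)) {
      tidy(uniformity) %>% mutate(test = "chromosome_uniformity", .before = 1)
    },
    tidy(subgenome$test) %>% mutate(test = "subgenome_balance", .before = 1)
  )

  files <- c(
    exclusions = "exclusions.tsv", clusters = "clusters.tsv",
    hotspots = "hotspots.tsv", metaqtl = "metaqtl.tsv",
    trait_counts = "trait_counts.tsv", tests = "chisq_tests.tsv",
    homoeologs = "homoeologs.tsv"
  )
  files <- setNames(file.path(config$out_dir, files), names(files))
  write_exclusion_report(projection, files["exclusions"])
  readr::write_tsv(clusters, files["clusters"])
  readr::write_tsv(hotspots, files["hotspots"])
  readr::write_tsv(metaqtl, files["metaqtl"])
  readr::write_tsv(trait_table, files["trait_counts"])
  readr::write_tsv(tests, files["tests"])
  readr::write_tsv(homoeologs, files["homoeologs"])

  manifest <- list(
    package_version = as.character(utils::packageVersion("cottonqtl")),
    inputs = list(
      map_file = config$map_file,
      qtl_file = config$qtl_file,
      map_md5 = unname(tools::md5sum(config$map_file)),
      qtl_md5 = unname(tools::md5sum(config$qtl_file))
    ),
    seeds = list(detection = config$detection$seed, meta = config$meta$seed),
    config = list(
      window = config$detection$window,
      min_cluster = config$detection$min_cluster,
      min_hotspot = config$detection$min_hotspot,
      min_traits = config$detection$min_traits,
      membership = config$detection$membership,
      kmax = config$meta$kmax,
      criterion = config$meta$criterion,
      alpha = config$alpha,
      overlap_cm = config$overlap_cm
    ),
    counts = list(
      parsed = nrow(records),
      kept = nrow(projection$kept),
      excluded = nrow(projection$excluded),
      clusters = nrow(clusters),
      hotspots = nrow(hotspots),
      metaqtl = nrow(metaqtl)
    ),
    output_md5 = as.list(setNames(unname(tools::md5sum(unname(files))),
                                  names(files)))
  )
  stopifnot(manifest$counts$parsed ==
              manifest$counts$kept + manifest$counts$excluded)
  manifest_file <- file.path(config$out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_file)

  result <- structure(list(
    manifest = manifest, projection = projection, clusters = clusters,
    hotspots = hotspots, metaqtl = metaqtl, trait_table = trait_table,
    tests = tests, homoeologs = homoeologs,
    files = c(files, manifest = manifest_file)
  ), class = "qtl_pipeline")
  stage_msg(v, "pipeline complete; outputs in %s", config$out_dir)
  invisible(result)
}

#' @export
print.qtl_pipeline <- function(x, ...) {
  cat("<qtl_pipeline>\n")
  cat(paste0("  ", render_summary(x)[1:6], collapse = "\n"), "\n  ...\n")
  invisible(x)
}

#' Render a human-readable pipeline summary
#'
#' Produces per-chromosome sections listing clusters, hotspots (grouped by
#' trait with their genome-wide numbering), the selected number of meta-QTL
#' and the genome-distribution tests.
#'
#' @param result A `qtl_pipeline` from [run_pipeline()].
#' @return Character vector of report lines.
#' @export
render_summary <- function(result) {
  counts <- result$manifest$counts
  lines <- c(
    "Meta-QTL pipeline summary",
    sprintf("records: %d parsed, %d kept, %d excluded",
            counts$parsed, counts$kept, counts$excluded),
    sprintf("calls: %d cluster(s), %d hotspot(s)",
            counts$clusters, counts$hotspots)
  )
  for (i in seq_len(nrow(result$tests))) {
    t <- result$tests[i, ]
    lines <- c(lines, sprintf(
      "%s: X^2 = %.2f (df %d, critical %.2f) -> %s", t$test, t$statistic,
      t$df, t$critical, if (t$exceeds) "non-uniform" else "uniform"))
  }
  chroms <- unique(result$metaqtl$chromosome)
  chroms <- chroms[order(chrom_number(chroms))]
  for (chrom in chroms) {
    lines <- c(lines, sprintf("-- %s --", chrom))
    cl <- result$clusters %>% filter(.data$chromosome == chrom)
    if (nrow(cl) == 0) {
      lines <- c(lines, "no clusters detected")
    } else {
      lines <- c(lines, sprintf("cluster %s: %.0f-%.0f cM, %d QTL (%d traits)",
                                cl$name, cl$start_cM, cl$end_cM, cl$n_qtl,
                                cl$n_traits))
    }
    hs <- result$hotspots %>% filter(.data$chromosome == chrom)
    if (nrow(hs) > 0) {
      hs <- hs[order(hs$trait, hs$start_cM), ]
      lines <- c(lines, sprintf("hotspot %s: %.0f-%.0f cM, %d QTL",
                                hs$name, hs$start_cM, hs$end_cM, hs$n_qtl))
    }
    k <- unique(result$metaqtl$K[result$metaqtl$chromosome == chrom])
    lines <- c(lines, sprintf("meta-model: K = %d meta-QTL selected", k))
  }
  if (length(chroms) == 0 && counts$clusters == 0) {
    lines <- c(lines, "no clusters detected")
  }
  lines
}

#' Summaries of the packaged reference catalogue
#'
#' Regenerates the headline numbers of the reference analysis from the
#' packaged tables alone: study and QTL totals, per-trait QTL totals,
#' cluster/hotspot totals, per-chromosome tallies and per-trait hotspot
#' counts.
#'
#' @return A list with `n_studies`, `total_qtl`, `trait_totals`,
#'   `n_clusters`, `n_hotspots`, `hotspots_by_trait` and `tallies`.
#' @export
cotton_reference_summary <- function() {
  tables <- cotton_tables()
  totals <- table_totals(tables$trait_counts)
  stopifnot(sum(tables$studies$n_qtl) == totals$grand_total)
  list(
    n_studies = nrow(tables$studies),
    total_qtl = totals$grand_total,
    trait_totals = totals$col_totals,
    chromosome_totals = totals$row_totals,
    n_clusters = nrow(tables$clusters),
    n_hotspots = nrow(tables$hotspots),
    hotspots_by_trait = count(tables$hotspots, .data$trait, name = "n"),
    tallies = tables$tallies
  )
}
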