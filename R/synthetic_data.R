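#' Specification for a synthetic multi-study QTL collection
#'
#' Describes a simulated genome and QTL collection emulating the
#' statistical structure of pooled cotton QTL studies: per-chromosome maps
#' of roughly 80-150 cM, QTL positions drawn from planted Gaussian regions
#' plus a uniform background, heavy-tailed (log-normal) CI widths, trait
#' labels from the 43-code vocabulary and round-robin study provenance.
#'
#' @param n_chromosomes Number of chromosomes (1-26); default 26.
#' @param length_range Chromosome length range in cM; default `c(80, 150)`.
#' @param n_studies Number of source studies to attribute records to;
#'   default 42.
#' @param planted Optional tibble of planted regions with columns
#'   `chromosome`, `center_cM`, `sd_cM`, `traits` (semicolon-joined trait
#'   codes) and `n_per_trait`.
#' @param background_rate Expected background QTL per 100 cM per background
#'   trait; the count per chromosome and trait is Poisson with mean
#'   `background_rate * length / 100`, matching the uniform null of the
#'   false-positive-rate estimator. Default 0.1.
#' @param background_traits Trait codes receiving background QTL; default
#'   the full vocabulary.
#' @param ci_width_median Median CI width in cM (log-normal); default 15.
#' @param ci_width_sdlog Log-scale sd of the CI width; default 0.5.
#' @param missing_position_frac Fraction of records emitted with a blank
#'   position (flanking markers supplied instead).
#' @param missing_ci_frac Fraction of records emitted with a blank CI.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_chromosomes = 26, length_range = c(80, 150),
                           n_studies = 42, planted = NULL,
                           background_rate = 0.1, background_traits = NULL,
                           ci_width_median = 15, ci_width_sdlog = 0.5,
                           missing_position_frac = 0, missing_ci_frac = 0) {
  stopifnot(n_chromosomes >= 1, n_chromosomes <= 26,
            length(length_range) == 2, length_range[1] > 0,
            length_range[1] <= length_range[2],
            n_studies >= 1, background_rate >= 0,
            ci_width_median > 0, ci_width_sdlog >= 0,
            missing_position_frac >= 0, missing_position_frac <= 1,
            missing_ci_frac >= 0, missing_ci_frac <= 1)
  if (is.null(background_traits)) background_traits <- trait_vocabulary()$trait
  if (is.null(planted)) {
    planted <- tibble(chromosome = character(), center_cM = numeric(),
                      sd_cM = numeric(), traits = character(),
                      n_per_trait = integer())
  }
  planted <- as_tibble(planted)
  stopifnot(all(c("chromosome", "center_cM", "sd_cM", "traits",
                  "n_per_trait") %in% names(planted)),
            all(planted$n_per_trait >= 0), all(planted$sd_cM >= 0))
  structure(list(
    n_chromosomes = as.integer(n_chromosomes), length_range = length_range,
    n_studies = as.integer(n_studies), planted = planted,
    background_rate = background_rate, background_traits = background_traits,
    ci_width_median = ci_width_median, ci_width_sdlog = ci_width_sdlog,
    missing_position_frac = missing_position_frac,
    missing_ci_frac = missing_ci_frac
  ), class = "synthetic_spec")
}

#' Generate a synthetic consensus map
#'
#' Draws a consensus map with `n_chromosomes` chromosomes whose lengths are
#' uniform in `length_range`, markers spaced 1-5 cM apart (uniform), and
#' the first marker of each chromosome at 0 cM. Deterministic given the
#' seed.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return A `consensus_map` tibble, as from [read_map_file()].
#' @export
generate_map <- function(spec, seed = 20131111) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(as.integer(seed), {
    out <- purrr::map_dfr(seq_len(spec$n_chromosomes), function(i) {
      chrom <- paste0("c", i)
      len <- runif(1, spec$length_range[1], spec$length_range[2])
      gaps <- 0
      while (sum(gaps) < len) gaps <- c(gaps, runif(1, 1, 5))
      gaps <- gaps[cumsum(gaps) <= len]
      tibble(
        chromosome = chrom,
        marker = sprintf("%s_M%03d", chrom, seq_along(gaps)),
        distance_from_previous_cM = gaps,
        position_cM = cumsum(gaps)
      )
    })
    new_consensus_map(out)
  })
}

# truncated normal draw via inverse CDF (deterministic given RNG state)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  p <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(p, mean, sd)
}

#' Generate a synthetic multi-study QTL collection with ground truth
#'
#' Draws QTL records on the given map: planted QTL positions are normal
#' around each planted region's center (truncated to the chromosome),
#' background QTL counts are Poisson per chromosome and trait with uniform
#' positions, CI widths are log-normal and centered on the position
#' (clipped to the chromosome), and study labels are assigned round-robin.
#' A configurable fraction of records is emitted with the position and/or
#' CI blanked and the nearest flanking markers supplied instead, so the
#' projection stage is exercised.
#'
#' @param spec A [synthetic_spec()].
#' @param map A `consensus_map` from [generate_map()].
#' @param seed Integer seed.
#' @return A list with `records` (a QTL record tibble, see
#'   [read_qtl_file()]) and `truth` (a `qtl_ground_truth`: tibbles
#'   `regions` and `positions` carrying each record's true position and
#'   planted-region membership).
#' @export
generate_qtl_set <- function(spec, map, seed = 20131111) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(map, "consensus_map"))
  lengths <- map_lengths(map)
  len_of <- setNames(lengths$length_cM, lengths$chromosome)
  planted <- spec$planted
  if (nrow(planted) > 0) {
    bad <- planted$center_cM < 0 | planted$center_cM > len_of[planted$chromosome]
    if (any(bad)) {
      abort(sprintf("planted center %.1f cM is off chromosome %s",
                    planted$center_cM[which(bad)[1]],
                    planted$chromosome[which(bad)[1]]))
    }
  }
  withr::with_seed(as.integer(seed), {
    draws <- list()
    if (nrow(planted) > 0) {
      draws <- purrr::map(seq_len(nrow(planted)), function(r) {
        traits <- strsplit(planted$traits[r], ";")[[1]]
        L <- len_of[[planted$chromosome[r]]]
        purrr::map_dfr(traits, function(tr) {
          n <- planted$n_per_trait[r]
          tibble(
            chromosome = planted$chromosome[r],
            trait = tr,
            true_position_cM = rtruncnorm(n, planted$center_cM[r],
                                          planted$sd_cM[r], 0, L),
            origin = "planted",
            region_id = sprintf("region-%d", r)
          )
        })
      })
    }
    background <- purrr::map_dfr(lengths$chromosome, function(chrom) {
      L <- len_of[[chrom]]
      counts <- rpois(length(spec$background_traits),
                      spec$background_rate * L / 100)
      purrr::map_dfr(which(counts > 0), function(ti) {
        tibble(
          chromosome = chrom,
          trait = spec$background_traits[ti],
          true_position_cM = runif(counts[ti], 0, L),
          origin = "background",
          region_id = NA_character_
        )
      })
    })
    all <- bind_rows(c(draws, list(background)))
    if (nrow(all) == 0) {
      abort("spec generated zero QTL; increase background_rate or plant regions")
    }
    all <- all[order(chrom_number(all$chromosome), all$true_position_cM), ,
               drop = FALSE]
    n <- nrow(all)
    all$qtl_name <- sprintf("q%04d", seq_len(n))
    all$study_id <- sprintf("S%02d", (seq_len(n) - 1) %% spec$n_studies + 1)

    width <- rlnorm(n, log(spec$ci_width_median), spec$ci_width_sdlog)
    L <- len_of[all$chromosome]
    ci_lo <- pmax(all$true_position_cM - width / 2, 0)
    ci_hi <- pmin(all$true_position_cM + width / 2, L)

    # nearest map markers below/above the true position (for blanked fields)
    flank <- purrr::map_dfr(seq_len(n), function(i) {
      mk <- map[map$chromosome == all$chromosome[i], ]
      below <- which(mk$position_cM <= all$true_position_cM[i])
      above <- which(mk$position_cM >= all$true_position_cM[i])
      tibble(
        flank_left = mk$marker[if (length(below)) max(below) else 1],
        flank_right = mk$marker[if (length(above)) min(above) else nrow(mk)]
      )
    })

    blank_pos <- runif(n) < spec$missing_position_frac
    blank_ci <- runif(n) < spec$missing_ci_frac

    records <- tibble(
      map_name = "synthetic",
      qtl_name = all$qtl_name,
      study_id = all$study_id,
      chromosome = all$chromosome,
      trait = all$trait,
      lod = round(runif(n, 2.5, 10), 2),
      r2 = round(runif(n, 0.03, 0.30), 3),
      method = sample(c("CIM", "MQM", "ICIM"), n, replace = TRUE),
      position_cM = ifelse(blank_pos, NA_real_, all$true_position_cM),
      ci_lo_cM = ifelse(blank_ci, NA_real_, ci_lo),
      ci_hi_cM = ifelse(blank_ci, NA_real_, ci_hi),
      flank_left = ifelse(blank_pos | blank_ci, flank$flank_left,
                          NA_character_),
      flank_right = ifelse(blank_pos | blank_ci, flank$flank_right,
                           NA_character_)
    )

    regions <- if (nrow(planted) > 0) {
      planted %>%
        mutate(region_id = sprintf("region-%d", row_number())) %>%
        left_join(
          all %>%
            filter(.data$origin == "planted") %>%
            group_by(.data$region_id) %>%
            summarise(n_qtl = n(),
                      members = paste(.data$qtl_name, collapse = ";"),
                      .groups = "drop"),
          by = "region_id"
        ) %>%
        select("region_id", "chromosome", "center_cM", "sd_cM", "traits",
               "n_qtl", "members")
    } else {
      tibble(region_id = character(), chromosome = character(),
             center_cM = numeric(), sd_cM = numeric(), traits = character(),
             n_qtl = integer(), members = character())
    }
    truth <- structure(
      list(regions = regions,
           positions = all[, c("qtl_name", "chromosome", "true_position_cM",
                               "origin", "region_id")]),
      class = "qtl_ground_truth")
    list(records = records, truth = truth)
  })
}

#' Precision/recall of calls against planted ground truth
#'
#' A planted region counts as recovered when some call on its chromosome
#' has an interval midpoint within `match_cm` of the region center; a call
#' counts as matched under the same rule. Recall is recovered regions over
#' planted regions; precision is matched calls over calls (reported as 0
#' and flagged when there are no calls).
#'
#' @param truth A `qtl_ground_truth` from [generate_qtl_set()].
#' @param calls A tibble of calls with `chromosome`, `start_cM`, `end_cM`.
#' @param match_cm Matching tolerance in cM; default 10.
#' @return A one-row tibble: `n_planted`, `n_calls`, `n_recovered`,
#'   `n_matched`, `recall`, `precision`, `precision_defined`.
#' @export
recovery_report <- function(truth, calls, match_cm = 10) {
  regions <- truth$regions
  mid <- (calls$start_cM + calls$end_cM) / 2
  near <- function(chrom, center) {
    any(calls$chromosome == chrom & abs(mid - center) <= match_cm)
  }
  recovered <- purrr::map2_lgl(regions$chromosome, regions$center_cM, near)
  matched <- purrr::map_lgl(seq_len(nrow(calls)), function(i) {
    any(regions$chromosome == calls$chromosome[i] &
          abs(regions$center_cM - mid[i]) <= match_cm)
  })
  precision_defined <- nrow(calls) > 0
  tibble(
    n_planted = nrow(regions),
    n_calls = nrow(calls),
    n_recovered = sum(recovered),
    n_matched = sum(matched),
    recall = if (nrow(regions) > 0) mean(recovered) else NA_real_,
    precision = if (precision_defined) mean(matched) else 0,
    precision_defined = precision_defined
  )
}
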