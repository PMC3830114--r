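#' Tabulate QTL counts by chromosome and trait
#'
#' Builds the trait-by-chromosome count matrix of a projected QTL set in
#' wide form: one row per chromosome (all 26, including empty ones), one
#' column per trait code (all 43). The grand total equals the number of
#' records.
#'
#' @param records Tibble of kept (projected) QTL records.
#' @param vocabulary Trait vocabulary, see [trait_vocabulary()].
#' @return A 26 x 44 tibble (`chromosome` plus one count column per trait).
#' @export
tabulate_qtl <- function(records, vocabulary = trait_vocabulary()) {
  chroms <- chromosome_codes()
  counts <- table(factor(records$chromosome, levels = chroms),
                  factor(records$trait, levels = vocabulary$trait))
  out <- as_tibble(as.data.frame.matrix(counts), rownames = "chromosome")
  out[-1] <- lapply(out[-1], as.integer)
  out
}

#' Row, column and grand totals of a trait-by-chromosome table
#'
#' @param table A wide count table as returned by [tabulate_qtl()] or
#'   [cotton_trait_counts()].
#' @return A list with `row_totals` (per chromosome), `col_totals` (per
#'   trait) and `grand_total`.
#' @export
table_totals <- function(table) {
  mat <- as.matrix(table[-1])
  list(
    row_totals = tibble(chromosome = table$chromosome,
                        total = as.integer(rowSums(mat))),
    col_totals = tibble(trait = colnames(mat),
                        total = as.integer(colSums(mat))),
    grand_total = sum(mat)
  )
}

#' Chi-square test of uniformity over categories
#'
#' Tests observed counts against the uniform expectation (total / number of
#' categories) and reports the statistic together with the critical value
#' of the chi-square distribution at significance level `alpha` with
#' `df = #categories - 1`.
#'
#' @param counts Non-negative integer counts (at least 2 categories, total
#'   > 0).
#' @param alpha Significance level for the critical value.
#' @return A `chisq_report` list with elements `statistic`, `df`,
#'   `expected`, `critical`, `alpha`, `exceeds` and `p_value`; [tidy()]
#'   gives a one-row tibble.
#' @export
#' @examples
#' uniformity_chisq(c(536, 687))  # statistic ~18.64, critical 3.84
uniformity_chisq <- function(counts, alpha = 0.05) {
  if (length(counts) < 2) abort("at least 2 categories are required")
  if (any(counts < 0) || sum(counts) <= 0) {
    abort("counts must be non-negative with a positive total")
  }
  ht <- suppressWarnings(chisq.test(counts))
  df <- length(counts) - 1
  critical <- qchisq(1 - alpha, df)
  structure(list(
    statistic = unname(ht$statistic),
    df = df,
    expected = unname(ht$expected),
    critical = critical,
    alpha = alpha,
    exceeds = unname(ht$statistic) > critical,
    p_value = unname(ht$p.value)
  ), class = "chisq_report")
}

#' @export
print.chisq_report <- function(x, ...) {
  cat(sprintf(
    "<chisq_report> X^2 = %.3f, df = %d, critical(%g) = %.3f -> %s\n",
    x$statistic, x$df, x$alpha, x$critical,
    if (x$exceeds) "non-uniform" else "consistent with uniform"))
  invisible(x)
}

#' @describeIn uniformity_chisq One-row tibble of the test.
#' @param x A `chisq_report`.
#' @param ... Unused.
#' @method tidy chisq_report
#' @export
tidy.chisq_report <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, critical = x$critical,
         alpha = x$alpha, exceeds = x$exceeds, p_value = x$p_value)
}

#' Homoeologous chromosome pairs of tetraploid cotton
#'
#' The 13 A-subgenome / D-subgenome chromosome pairs of allotetraploid
#' cotton. Chromosomes c1-c13 form the A subgenome and c14-c26 the D
#' subgenome.
#'
#' @return A tibble with columns `pair`, `a_chromosome`, `d_chromosome`.
#' @export
homoeolog_map <- function() {
  tibble(
    pair = 1:13,
    a_chromosome = paste0("c", 1:13),
    d_chromosome = c("c15", "c14", "c17", "c22", "c19", "c25", "c16", "c24",
                     "c23", "c20", "c21", "c26", "c18")
  )
}

#' Subgenome of each chromosome code
#'
#' @param chromosome Character vector of chromosome codes.
#' @return `"A"` for c1-c13, `"D"` for c14-c26.
#' @export
subgenome_of <- function(chromosome) {
  ifelse(chrom_number(chromosome) <= 13, "A", "D")
}

#' QTL counts per subgenome with a balance test
#'
#' Sums the trait-by-chromosome table over the A (c1-c13) and D (c14-c26)
#' subgenomes and tests the two totals against an equal split (13
#' chromosomes each side, so expected counts are equal halves; df = 1,
#' critical 3.84 at alpha = 0.05).
#'
#' @param table A wide count table, see [tabulate_qtl()].
#' @param alpha Significance level.
#' @return A list with `n_a`, `n_d` and `test` (a `chisq_report`).
#' @export
subgenome_counts <- function(table, alpha = 0.05) {
  totals <- table_totals(table)$row_totals
  n_a <- sum(totals$total[subgenome_of(totals$chromosome) == "A"])
  n_d <- sum(totals$total[subgenome_of(totals$chromosome) == "D"])
  list(n_a = n_a, n_d = n_d,
       test = uniformity_chisq(c(n_a, n_d), alpha = alpha))
}

#' Compare cluster/hotspot calls between homoeologous chromosomes
#'
#' For each of the 13 A/D chromosome pairs, lists pairs of calls whose cM
#' intervals overlap after allowing `overlap_cm` of slack (two intervals
#' are shared when `max(start) <= min(end) + overlap_cm`). Coordinates are
#' compared raw; the slack absorbs the informal alignment of the two maps.
#' When both call sets carry a `trait` column the report flags shared
#' same-trait hotspots. The result is symmetric in pair order.
#'
#' @param calls A tibble of calls with columns `name`, `chromosome`,
#'   `start_cM`, `end_cM` and optionally `trait` (clusters and hotspots may
#'   be passed together via [dplyr::bind_rows()]).
#' @param pairs Homoeologous pair table, see [homoeolog_map()].
#' @param overlap_cm Slack in cM; default 10.
#' @return A tibble with one row per shared pair of calls: `pair`,
#'   `a_chromosome`, `d_chromosome`, `a_name`, `d_name`, the four interval
#'   bounds and `same_trait`.
#' @export
compare_homoeologs <- function(calls, pairs = homoeolog_map(),
                               overlap_cm = 10) {
  empty <- tibble(pair = integer(), a_chromosome = character(),
                  d_chromosome = character(), a_name = character(),
                  d_name = character(), a_start_cM = numeric(),
                  a_end_cM = numeric(), d_start_cM = numeric(),
                  d_end_cM = numeric(), same_trait = logical())
  if (nrow(calls) == 0) return(empty)
  if (!"trait" %in% names(calls)) calls$trait <- NA_character_
  out <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- calls %>% filter(.data$chromosome == pairs$a_chromosome[i])
    d <- calls %>% filter(.data$chromosome == pairs$d_chromosome[i])
    if (nrow(a) == 0 || nrow(d) == 0) return(NULL)
    grid <- tidyr::expand_grid(ai = seq_len(nrow(a)), di = seq_len(nrow(d)))
    shared <- pmax(a$start_cM[grid$ai], d$start_cM[grid$di]) <=
      pmin(a$end_cM[grid$ai], d$end_cM[grid$di]) + overlap_cm
    grid <- grid[shared, , drop = FALSE]
    if (nrow(grid) == 0) return(NULL)
    tibble(
      pair = pairs$pair[i],
      a_chromosome = pairs$a_chromosome[i],
      d_chromosome = pairs$d_chromosome[i],
      a_name = a$name[grid$ai],
      d_name = d$name[grid$di],
      a_start_cM = a$start_cM[grid$ai],
      a_end_cM = a$end_cM[grid$ai],
      d_start_cM = d$start_cM[grid$di],
      d_end_cM = d$end_cM[grid$di],
      same_trait = !is.na(a$trait[grid$ai]) & !is.na(d$trait[grid$di]) &
        a$trait[grid$ai] == d$trait[grid$di]
    )
  })
  if (nrow(out) == 0) empty else out
}
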