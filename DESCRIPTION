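Package: cottonqtl
Title: Genome-Wide Meta-QTL Analysis for Tetraploid Cotton
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide meta-analysis of quantitative
    trait loci (QTL) collected from heterogeneous mapping studies in tetraploid
    cotton (Gossypium). Projects published QTL onto a consensus linkage map with
    explicit placement, confidence-interval substitution and exclusion rules;
    calls multi-trait QTL clusters and single-trait hotspots with sliding
    20-centimorgan window rules and a Monte-Carlo false-positive-rate estimate;
    fits a per-chromosome maximum-likelihood Gaussian mixture meta-model with
    information-criterion selection of the number of meta-QTL; and tests the
    genome-wide QTL distribution (chromosome uniformity, A/D subgenome balance,
    homoeologous-pair sharing). Ships transcriptions of the published study
    list, trait-by-chromosome count matrix and cluster/hotspot catalogue as
    fixtures, plus a synthetic-data generator with planted structure so every
    pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
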