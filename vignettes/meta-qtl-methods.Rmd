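---
title: "Methods: meta-QTL analysis on a consensus cotton map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-QTL analysis on a consensus cotton map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cottonqtl)
```

## The problem

QTL mapping studies in tetraploid cotton report loci for fiber quality,
yield, seed, morphology, resistance and drought traits on many different
linkage maps. Pooling them requires (i) projecting every reported QTL onto
one consensus map, (ii) deciding which co-located reports constitute a real
aggregation, and (iii) condensing each aggregation into a consensus
position with an uncertainty interval. `cottonqtl` implements each step
with explicit, testable rules. Coordinates are continuous centimorgans (cM)
on closed intervals; each chromosome's origin is its first consensus
marker, so positions live in `[0, length]`.

## Projection rules and their rationale

Source studies differ in what they report. The projection stage
(`place_qtl()`, `project_qtl()`) resolves records in a fixed order:

1. A record with an explicit position and CI is never moved.
2. A missing position becomes the midpoint of the two flanking markers.
   Flanking markers bracket the reported locus, and without the original
   likelihood curve the midpoint is the only placement that does not
   invent information.
3. A missing CI becomes the flanking-marker interval — the tightest
   region the source data actually supports.
4. If a substituted value leaves the position outside the CI, the CI is
   widened minimally to cover it, preserving the record invariant
   `ci_lo <= position <= ci_hi`.

Exclusions are reported, never silently applied: `MARKER_NOT_ON_MAP`
(a named flank absent from the consensus map), `OUT_OF_RANGE` (position
outside the chromosome span), `MULTI_LOCATION` (one QTL name at two or
more distinct positions on a chromosome within one study), and
`UNRESOLVABLE` (no position/CI and no usable flanks). For multi-location
names *all* copies are dropped: there is no principled way to pick the
true copy, and keeping both would double-count one locus. Projection is
idempotent — re-projecting the kept set excludes nothing — and this is
enforced by test.

## Window detection of clusters and hotspots

Detection asks where QTL pile up within a region of width `window`
(default **20 cM**, the scale at which large aggregates of cotton QTL are
typically observed, and wide enough that a wide-CI QTL may plausibly sit
anywhere inside one region). Candidate windows `[x_i, x_i + window]` are
anchored at the QTL positions themselves rather than on a grid: this makes
calls deterministic, order-free, and independent of any binning origin.
Windows holding at least `min_cluster` QTL qualify; overlapping qualifying
windows merge into one call (one call per contiguous dense region), and
the reported interval is the min-to-max span of member positions.

* **Clusters** scan all traits jointly and additionally require
  `min_traits` (default 2) distinct trait types — a cluster is by
  definition a multi-trait aggregation.
* **Hotspots** scan one trait at a time with threshold `min_hotspot`.
  Both thresholds default to **4**: the cluster definition requires four
  or more QTL, and the smallest hotspot in the reference catalogue also
  carries 4.

One consequence of the merge rule is worth stating: two dense regions
closer than one window width are reported as a single call, because a
window anchored at the tail of the first region necessarily qualifies and
overlaps the second. Manually curated catalogues sometimes split such
regions; this implementation deliberately does not, trading that
resolution for determinism.

Membership is by point position by default. The `ci-overlap` mode counts a
QTL toward a window whenever its CI intersects the window, for collections
where wide-CI QTL would otherwise be dropped from calls they plausibly
belong to; each record is then assigned to the single merged region its CI
overlaps most (ties toward the leftmost), so every QTL still appears in at
most one call.

Naming follows the field convention: clusters restart numbering per
chromosome (`c5-cluster-3`), hotspots carry one genome-wide counter per
trait in chromosome-then-position order (`c23-VW-Hotspot-5`), with display
labels `Micronaire`, `color` and `Leaf` for the `Micro`, `Color` and
`LeafMorph` codes.

`estimate_false_positive_rate()` quantifies the chance of a spurious call:
the fraction of Monte-Carlo replicates (default 10,000, seeded, default
seed 20131111) in which `n` uniformly placed QTL yield at least one
qualifying window. It is trait-blind by construction and is validated in
the tests against an independent high-replicate simulation and against the
empirical call rate on background-only synthetic data.

## The mixture meta-model

Within a chromosome, each projected QTL contributes an observation
`x_i ~ N(mu_{z_i}, sigma_i^2)` where `z_i` is its (unknown) meta-QTL and
`sigma_i` comes from its CI via `ci_to_sigma()`:
`sigma = (ci_hi - ci_lo) / (2 * qnorm((1 + level) / 2))`, level defaulting
to 0.95 since source studies rarely state one. This is the standard
meta-QTL formulation: the observation variances are *fixed* by the data
and the only free parameters are the component means `mu_k` (meta-QTL
positions) and mixing weights `pi_k`. LOD and R² are carried through
reports but never enter the likelihood — they are irrelevant to placement.

`fit_mixture()` maximizes the log-likelihood by EM. The E-step uses
log-sum-exp for stability; the M-step updates
`pi_k = mean_i r_ik` and the precision-weighted means
`mu_k = sum_i r_ik x_i / sigma_i^2 / sum_i r_ik / sigma_i^2`. The
log-likelihood is asserted non-decreasing at every iteration (a decrease
aborts the fit as a bug), and the K = 1 solution must equal the closed-form
inverse-variance weighted mean to 1e-6 cM — both are tested.

Numerical choices:

* **Initialization.** Restart 0 places the K means at the
  `(k - 0.5)/K` quantiles of the positions (deterministic); the remaining
  `restarts - 1` (default 10 total) jitter those quantiles with seeded
  normal noise, giving reproducible multi-start behavior. The best
  log-likelihood wins.
* **Convergence.** Absolute log-likelihood increase below `tol = 1e-8`,
  capped at `max_iter = 500` (a cap hit is reported, and warned about in
  the pipeline).
* **Collapse guard.** If a component's total responsibility falls below
  1e-6 it is re-seeded at the worst-fit observation, preventing empty
  components rather than letting a weight silently underflow.
* **Sigma floor.** `ci_to_sigma()` floors at 0.1 cM so zero-width CIs
  cannot create zero-variance components.

`select_model()` fits K = 1 .. min(kMax, n) — kMax defaults to **10** —
and picks the minimizer of the information criterion, AIC by default with
`p = 2K - 1` parameters (AICc and BIC selectable; AICc returns `Inf` when
`n <= p + 1`, which simply removes over-parameterized K from
consideration). Ties break toward smaller K, the conservative choice. A
`k_fixed` override supports the workflow where the analyst has already
decided the component count by inspection. Component intervals are
`mu_k ± 1.96 / sqrt(sum_i r_ik / sigma_i^2)`, clipped to the chromosome
when its length is supplied.

## Genome-distribution statistics

`tabulate_qtl()` always produces the full 26-chromosome × 43-trait grid so
that empty rows are visible, and conserves the record count. The
uniformity test compares per-chromosome totals to an equal expectation
(`chisq.test` under the hood; df = 25, critical 37.65 at alpha = 0.05);
the subgenome test compares the A (c1–c13) and D (c14–c26) totals to
equal halves — expected counts proportional to the 13:13 chromosome split,
giving df = 1 and critical 3.84. `compare_homoeologs()` intersects call
intervals across the 13 A/D pairs with a `overlap_cm` slack (default
10 cM) because the two subgenome maps are aligned only informally; the
report is symmetric in pair order.

The packaged reference tables carry two internal tensions worth knowing
about. The count matrix's subgenome sums are 536 (A) and 687 (D), and our
chi-square on them is 18.64 — the catalogue's own printed statistic is
18.72, which is not recoverable from these counts; the package always
reports its computed value. The matrix row sums also disagree with some
per-chromosome totals narrated alongside the original catalogue (e.g. 83
vs 75 on c14); the cell-level matrix is treated as authoritative
throughout.

## What the synthetic generator emulates — and what it does not

`generate_map()` / `generate_qtl_set()` emulate the statistical shape of a
pooled cotton QTL collection: 26 chromosomes of 80–150 cM (the span range
of the reference catalogue), markers every 1–5 cM, planted Gaussian QTL
groups plus a per-trait Poisson background with uniform positions (mean
`background_rate × length / 100`, the memoryless null matching the
false-positive estimator; default rate 0.1 per trait per 100 cM, which
yields a realistic handful of background QTL per chromosome), log-normal
CI widths (median 15 cM, sdlog 0.5 — a mix of tight and very wide
intervals, the heavy tail mimicking the least informative source studies),
42 round-robin study labels, and configurable fractions of records with
blanked positions/CIs plus nearest-flanking-marker annotations.

It does **not** simulate genotypes, phenotypes, segregation distortion,
marker-order conflicts between maps, or the interval-mapping step that
produced the source QTL. Consequently, passing the planted-recovery tests
shows that the meta-layer (projection, detection, meta-model) behaves
correctly on data with known structure; it does not validate the upstream
mapping quality of any real study, nor the biological reality of any
particular catalogued cluster.

`recovery_report()` scores calls by interval midpoint against planted
centers within `match_cm` (default 10 cM, half a window). With a dense
multi-trait background, merged calls stretch and midpoints drift, so
recovery statements are made in the low-background regime where planted
structure dominates.

## Simulation sizes

The test suite and acceptance script use deliberately small, fixed problem
sizes: 100-seed batches for K-selection accuracy (20 QTL, two components,
5-sigma separation) and planted-cluster recall (2 chromosomes, 3 planted
regions, low background), 300 background-only replicates against the
Monte-Carlo false-positive estimator (20,000 replicates), and 1,000 random
instances (≤ 12 QTL) for the window-scan/brute-force equivalence. These
sizes give stable Monte-Carlo error (binomial SE ≈ 1–3 points) while
keeping a full run in minutes on one core.

## Known limitations

* True map merging (re-projecting between source maps via shared markers)
  is out of scope; inputs are assumed to already be in consensus-map
  coordinates.
* The window rules are intentionally simple; no per-call significance is
  attached beyond the genome-null chance rate, and no multiple-testing
  correction is applied across traits.
* The mixture model treats CIs as symmetric normal intervals; skewed
  likelihood surfaces from the source studies are not representable.
* Adjacent dense regions closer than one window width merge into one call
  (see above), so counts of calls are conservative relative to manual
  curation.
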