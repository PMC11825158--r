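---
title: "Quantifying germ cells in immature testis sections: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying germ cells in immature testis sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tubulequant)
```

## The problem

Fertility preservation for prepubertal boys rests on counting the germ cells
(gonocytes and (pre)spermatogonia) that survive chemotherapy exposure,
cryopreservation, or in vitro culture of testicular tissue. The established
counting conventions — spermatogonia per round tubular cross-section (S/T)
and the fertility index (FI) — only use *round* tubule profiles, i.e.
cross-sections cut nearly perpendicular to the tubule axis. Immature human
tissue, and especially the ~1 mm³ fragments used in organotypic culture,
often contains very few round profiles, which forces samples out of the
analysis. Tubular germ cell density, which normalises the count by the total
tubular area regardless of profile shape, removes that requirement.

`tubulequant` implements all four quantification metrics over polygon/point
annotation exports (QuPath-style GeoJSON or plain CSV tables), so that the
manual measurement steps — outlining tubules, measuring their longest and
shortest diameters, clicking positively stained cells — are replaced by
their computational equivalents on the annotation geometry:

* **Method 1, tubular germ cell density** = germ cells / total tubular area
  (cells per mm², all tubule shapes);
* **Method 2, S/T** = germ cells in round tubules / number of round tubules;
* **Method 3, fertility index** = 100 × round tubules containing ≥1 germ
  cell / number of round tubules (percent);
* **Method 4, round tubular germ cell density** = germ cells in round
  tubules / round tubular area (cells per mm²).

A tubule is *round* when its longest/shortest diameter ratio is strictly
below 1.5. A metric whose denominator is zero is reported missing, never an
error.

## Geometry conventions

Coordinates are continuous Cartesian millimetres with y increasing downward,
as in image exports; there are no pixel-grid semantics. The manual
caliper measurement of "longest and shortest diameters" is formalised as the
maximum and minimum **Feret diameters** of the outline's convex hull: the
maximum is the largest vertex-pair distance of the hull, the minimum is the
smallest width over all directions, computed exactly by rotating calipers
over hull edges (convexity makes calipers exact). Area uses the true polygon
(shoelace formula); diameters use the hull, because manual diameters span
the shape, not its concavities. Both are oracle-tested: the maximum against
an exhaustive vertex-pair search, the minimum against a 36,000-direction
brute-force width sweep. The uniform sweep can only overestimate the true
minimum, and at kinked width minima its grid resolution
(≈ diameter·π/36,000) can exceed the comparison tolerance; the test suite
escalates to a finer sweep in exactly that situation rather than loosening
the tolerance.

Cell marks are assigned to tubules with an even-odd point-in-polygon test
under a **closed-region** convention — marks on the outline count as inside,
because annotators click nuclei straddling the boundary. If outlines overlap
(the annotation tools do not prevent it), a cell in the intersection goes to
the first containing tubule in ascending `tubule_id` order, with a warning;
cells in no tubule are interstitial and never enter any metric.

Tubules clipped by the section edge must be excluded ("incomplete basement
membrane"). An annotator-provided intact flag always wins; otherwise a
tubule is excluded when any outline vertex lies outside the region of
interest or within `edge_tolerance` (default 0.002 mm) of its boundary. The
tolerance is configurable because the manual intactness call is visual, not
metric.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `roundness_threshold` | 1.5 | strict `<` on the diameter ratio; a ratio of exactly 1.5 is *not* round |
| `edge_tolerance` | 0.002 mm | distance to the ROI boundary that marks a tubule as edge-clipped |
| `min_round_tubules` | 25 | below this, the `few_round_tubules` QC flag is raised |
| `min_total_area_mm2` | 0.015 (fetal), 0.003 (prepubertal) | below this, the `small_total_area` QC flag is raised |
| `pooling_mode` | `per_section_mean` | how sections aggregate to samples |
| `alpha` | 0.05 | significance level for all tests and the normality gate |

QC flags never exclude data automatically: the 25-round-tubule and
minimum-area conventions are reporting thresholds, and sub-threshold samples
are analysed separately (see the correlation strata) rather than discarded.

Aggregation to sample level defaults to the unweighted mean of defined
section-level values, matching the "mean value over all fragments from an
individual" convention of the study designs this package targets; sections
where a metric is undefined are omitted from that metric's mean. A
`pooled_counts` mode (sum counts and areas across sections, then reapply the
formulas) is provided because within-sample pooling is a genuinely open
choice; it weights sections by their tubular area instead of equally.

## Statistics

`compare_groups()` mirrors the analysis pipeline common in this literature:
per-group Shapiro–Wilk tests at `alpha` gate between a parametric and a
non-parametric branch. When every group passes, an additive two-factor ANOVA
with condition and subject as crossed factors is fitted — a randomized-block
model, chosen because in these designs every subject contributes tissue to
every condition — followed by Tukey's studentized-range pairwise
comparisons on condition. Otherwise Kruskal–Wallis on condition is followed
by Dunn's rank-based pairwise test with Bonferroni adjustment over all
pairs (the adjustment variant is a package choice; Dunn's test admits
several). Groups with fewer than 3 values or zero variance cannot be
assessed by Shapiro–Wilk and pass the gate; with zero residual variance the
condition effect is exact and the omnibus p-value is reported as 0. The
branch taken is always recorded in the result and the serialized output.

Method agreement uses Pearson's product-moment correlation of Methods 2–4
against Method 1 on sample-level values (one point per subject × condition),
overall and stratified into `< 25` / `>= 25` total round tubules — strict
`<` against the threshold, matching the reporting convention for
sub-threshold samples. Strata with fewer than 3 pairs are reported with
`r` and `p` undefined rather than dropped. The two-sided p-value comes from
the t transform on n−2 degrees of freedom, and the least-squares line is
reported for the best-fit overlay.

## The synthetic-data generator

Because annotated human tissue data are not redistributable, every stage is
validated against a simulator whose ground truth is analytic:

* **Tubule profiles are ellipses** (64-gon polygons): the round/elongated
  dichotomy is an axis-ratio statement, and ellipses make the true ratio,
  area and expected counts exact. Profile areas are lognormal (median
  0.005 mm², ≈ 80 µm across — typical of immature seminiferous cords);
  axis ratios are 1 + lognormal, so the round fraction is controlled
  analytically via `aspect_meanlog_for_round_fraction()`.
* **Placement** is dart-throwing with a conservative bounding-circle
  separation test (no overlaps, by construction) in a 1.5 × 1.5 mm section;
  profiles crossing the section boundary are clipped to it and ground-truth
  flagged non-intact, emulating edge-incomplete tubules.
* **Cells are a Poisson process** inside each profile with intensity
  `density` per mm² of *tubular* area (Method 1's denominator), placed
  uniformly by rejection sampling; a negative-binomial option adds
  overdispersion. Cell marks carry AP2γ/MAGE-A4 labels in a configurable
  proportion. Density is per tubule area, not section area, so Method 1
  recovers it without geometric bias.
* **Study structure**: a once-drawn multiplicative lognormal subject effect
  (mean 1) times a per-condition multiplier; each subject × condition sample
  gets 4 sections (two sections from each of two replicate fragments). RNG
  streams are keyed by (seed, subject, condition, section), so adding
  sections never perturbs existing ones and a seed reproduces a study
  byte-identically.

Two presets encode the regimes the package targets. `fetal_chemo` uses a
control density of 690.2 cells/mm² with multipliers 0.7052 (cisplatin) and
0.7212 (carboplatin) — the ratios of the reported group means for that
experimental system. `prepubertal_cryo` uses base density 1175 cells/mm²
with multipliers 1 / 0.800 / 0.530 / 0.514 for fresh control, cryopreserved,
fresh-cultured and cryopreserved-cultured tissue; the four-condition pattern
is taken from the round-tubular-density means because a complete
Method-1 pattern is not available for that design, and the preset is a
starting point, not a claim of distributional fidelity. The default
between-subject SD (0.25, multiplicative) reflects the large inter-patient
variability seen in immature testis tissue.

What the simulator does **not** emulate: spatial clustering of germ cells
within tubules (a uniform default; a basement-membrane bias is biologically
plausible but not modelled), non-elliptical or concave tubule outlines,
annotation errors (missed or double-clicked cells, sloppy outlines), and
section-to-section correlation within a tissue block beyond the shared
density. Passing the simulation-based tests therefore demonstrates that the
*computational* pipeline is correct and that the metrics behave as designed
under a controlled point-process model — not that any particular biological
effect size will be detected in real tissue.

## Validation properties and problem sizes

The test suite asserts, among others:

* Feret oracle equivalence on 500 random convex and star-convex polygons;
* the strict 1.5 roundness boundary on ellipse 64-gons with axis ratios
  1.49 and 1.51;
* the algebraic identities `method2 = method4 × mean round-tubule area`,
  `method1 = method4` when every tubule is round, `method3 ∈ [0, 100]`;
* unit-scale equivariance (Methods 2–3 invariant, Methods 1 and 4 scale as
  1/s²);
* recovery of a 690 cells/mm² true density within 2% by the full pipeline
  over 300 simulated sections;
* the sampling-efficiency property that motivates Method 1: with fewer than
  25% of profiles round, the across-section variance of Method 4 exceeds
  that of Method 1 in ≥95% of 200-section experiments over 20 seeds;
* type-I calibration of the group comparison at 5% ± 3 points over 500
  permuted-label replicates;
* direction and significance recovery of the platinum-exposure effect under
  the `fetal_chemo` preset with low (0.05) subject noise over 50 study
  seeds;
* byte-identical reruns of the full simulate → quantify → compare →
  correlate chain at a fixed seed.

The problem sizes (300 sections for recovery, 20 × 200 sections for the
variance property, 50 study seeds for effect recovery) were chosen so each
property's sampling error is comfortably below the margin being asserted
while the whole suite stays quick to run.

## Numerical choices and degenerate inputs

* Point-in-polygon boundary detection uses an absolute tolerance of
  10⁻¹² × the polygon's coordinate magnitude; coordinates are mm, so this
  is far below annotation precision.
* Degenerate (collinear or zero-area) polygons raise a geometry error
  naming the tubule; a section with zero intact tubules yields all-missing
  metrics and QC flags, not an exception.
* Identifiers are opaque strings ordered with locale-independent radix
  sorting, so cell-assignment tie-breaks do not depend on the session
  locale.
* Metrics CSVs are written as decimal strings with 12 significant digits;
  a write → read → write round trip is byte-identical.
* The placement sampler gives up on a tubule after 10,000 attempts and
  errors when more than half the requested tubules cannot be placed,
  advising a larger section or fewer tubules.

## Known limitations

* The minimum Feret diameter is computed on the convex hull; for strongly
  concave outlines the "shortest diameter" of the hull can exceed any
  internal waist of the shape. This matches manual caliper practice but is
  a convention, not a theorem about tubule anatomy.
* The intactness heuristic is vertex-based; an outline that crosses the ROI
  boundary between two interior vertices (possible only with very coarse
  outlines) would evade it. Annotator flags override it in both directions.
* `compare_groups()` fits an additive block model; a subject × condition
  interaction is not estimable with one sample per cell and is therefore
  not modelled.
* GeoJSON input is limited to Polygon (first ring) and Point features;
  MultiPolygon tubules and polygon holes are not supported.
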