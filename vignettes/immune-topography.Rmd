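---
title: "Methods: zone partitioning, zone scores, and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zone partitioning, zone scores, and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunotopo)
library(dplyr)
```

## The problem

Pancreatic ductal adenocarcinoma (PDAC) is largely refractory to immune
checkpoint therapy, and keratin 17 (K17) — a marker of the aggressive basal
molecular subtype — has been implicated in shaping the immune contexture of
several epithelial cancers. Multiplex immunohistochemistry (mIHC) produces
multi-class segmentation masks in which every pixel carries one of seven
roles: stroma, K17-positive tumor, K17-negative (panCK+) tumor, CD4+ helper
T cells, CD8+ cytotoxic T cells, CD16+CD163− (M1-like) macrophages, or
CD16+CD163+ (M2-like) macrophages. `immunotopo` quantifies, from such
masks, whether immune cells are differentially distributed around
K17-positive versus K17-negative tumor.

## The model

### Influence zones

Every tumor pixel belongs to its own marker (`TUMOR_POS` / `TUMOR_NEG`).
For every non-tumor pixel we compute two exact Euclidean distance fields,
`d_pos` and `d_neg`, to the nearest tumor pixel of each marker (distances to
the pixel *set*, which for exterior points equals the distance to the tumor
boundary). With `dmin = min(d_pos, d_neg)`:

* `dmin > depth_um` → `OUTSIDE_BAND` (beyond the tumor-associated stroma);
* `dmin ≤ contact_um` → contact shell (`CONTACT_POS` / `CONTACT_NEG`), the
  intratumoral compartment;
* otherwise → peritumoral band (`PERI_POS` / `PERI_NEG`).

The marker side is the argmin of the two fields. Exact ties (within
1e-9 µm, which makes the rule float-robust) are assigned to the
K17-positive side; because the biological signal of interest is immune
*depletion* near K17-positive tumor, sending ambiguous pixels to the
positive side can only attenuate that signal, so the tie rule is
conservative. Pixels excluded by an ROI carry an `EXCLUDED` label and enter
no numerator or denominator.

`depth_um` defaults to 25 µm: a sweep of band depths from 5 to 200 µm
(`depth_sweep()`) locates the largest K17-linked density differences at
shallow depths, and 25 µm corresponds to the scale of direct cell–cell
contact. `contact_um` defaults to 1.5 × the pixel pitch (≈ 0.52 µm at
0.346 µm/px). Exclusive multi-class masks make literal overlap of immune
and tumor pixels impossible, so "contact" must be a sub-pixel-scale
adjacency rule; 1.5 pixel pitches captures 8-connected neighbours (the
diagonal sits at √2 ≈ 1.41 pitches) and nothing farther.

### Zone scores

For immune class `i`, marker `M` and compartment, the Tumor/Stromal Zone
Score is

    ZS(i, M) = CellCount(i, M) / ZoneArea(M)

where the cell count is estimated from pixels: stained pixels are converted
to µm² via the resolution and divided by the average single-cell area —
circles of 8 µm diameter for lymphocytes (CD4, CD8) and 16 µm for
macrophages (CD16, CD163). Counting is pixel-level throughout; no instance
segmentation is attempted, and a connected-component counting mode is
deliberately out of scope.

Denominators: the peritumoral denominator is the full `PERI_M` band,
*including* immune pixels (they are stroma; excluding them would inflate
scores in dense infiltrates). The intratumoral denominator is the
`TUMOR_M` + `CONTACT_M` area, so intra scores are densities over the
marker's tumor territory. The source description of the denominator is
unambiguous only for the peritumoral band; treating the intra denominator
as tumor-plus-contact territory was a design decision, made so that intra
scores of the two markers remain comparable when their tumor areas differ.
Records with a zero denominator are omitted rather than emitted as NaN.

Scores are reported in cells/mm² (×10⁶ from cells/µm²). Ratios
`ZS(K17−)/ZS(K17+)` are a *presentation* layer: a zero positive-side score
makes the ratio undefined (flagged, excluded from plots) while the raw
scores stay in the cohort statistics.

### Cohort statistics

Per class and compartment the package reports the share of cases whose
K17-negative score strictly exceeds the K17-positive score (ties count as
not-higher; undefined pairs are excluded from both numerator and
denominator) and a classical two-sided paired t test on the raw score
differences. Degenerate inputs (all-zero or constant differences) are
flagged instead of erroring. The paired test runs on raw scores, matching
the plain description of the source protocol; no multiple-testing
correction is applied, and this is documented rather than hidden.
Spearman correlation (average ranks, two-sided p via the t approximation)
supports manual-versus-digital K17 score comparisons.

### Randomization null

To show an observed asymmetry is not an artifact of zone geometry, each
immune class's estimated cell equivalents are re-placed per replicate as
disks of the class geometry, uniformly over the pooled admissible
territory of their compartment — contact pixels of both markers for
intratumoral cells, peritumoral pixels of both markers for peritumoral
cells — keeping per-case totals fixed. Scores are recomputed from the
re-placed pixels and the statistic is `|ZS_neg − ZS_pos|`. The empirical p
uses the add-one estimator `(1 + #{null ≥ obs}) / (1 + n_reps)`, which can
never return 0. The number of replicates, the placement territory and the
statistic are all configuration, since no canonical choice exists.

## The synthetic generator

No real masks ship with the package, so every downstream stage is
validated on `simulate_case()` / `simulate_cohort()`, which emulate the
output of a multi-class segmentation ensemble:

* **Tumor nests** are unions of overlapping random ellipses; each connected
  nest is split into contiguous K17+/K17− subregions by a random chord so
  the realized K17-positive share tracks `k17pos_fraction` (±4 percentage
  points of per-nest jitter).
* **Immune cells** are placed by an inhomogeneous Poisson process on the
  stroma whose intensity at a pixel is `base_intensity × zone_modulation`
  when the nearest tumor boundary is K17-positive and `base_intensity`
  otherwise — `zone_modulation < 1` models exclusion. Intensities are
  defined on the *generator's* distance fields, so recovery tests are not
  circular in their parameters. A configurable fraction of cells is placed
  in the contact shell. Cells are disks (8/16 µm), never overwrite tumor,
  and satisfy a hard-core constraint (centre distance ≥ sum of radii) via
  rejection sampling: the Poisson count is drawn first and each cell is
  re-drawn on conflict, so realized counts stay Poisson as long as
  placement succeeds. A saturated contact shell spills cells into the open
  stroma; genuine saturation aborts with advice to lower intensities.
* **Ground truth** records per case/class/marker/compartment the placed
  count (attributed by disk centre — unambiguous for cells straddling a
  band edge) and the true zone areas.

Defaults describe the study conditions being emulated: 1000 × 1000 px at
0.346 µm/px (the scanner resolution of the source cohort's whole-slide
images, and the size of its training regions), 8 nests of 30 ± 8 µm
radius, a 50% K17-positive share, and baseline intensities of 200, 500,
150 and 300 cells/mm² for CD4, CD8, CD16 and CD163 — densities in the
range reported for immune infiltrates in PDAC stroma, with CD8 highest so
that the headline CD8 analyses are well powered per case.

What the generator does *not* emulate: chromogen appearance, stain noise,
segmentation errors, realistic cell shapes, or spatial clustering of
immune cells beyond the zone dependence. Passing recovery tests therefore
demonstrates that the *quantification* pipeline is correct and calibrated,
not that any particular segmentation model is accurate.

## Numerical choices

* Distance transforms use an exact Euclidean algorithm, verified
  pixel-for-pixel against an exhaustive minimum-over-sources oracle
  (`brute_force_zones()`) on random masks.
* A class absent from a mask yields an infinite distance field; the other
  marker then owns the entire band.
* Disk rasterization includes a pixel when its centre lies within the
  radius. Dot-annotation dilation rounds the radius to the nearest integer
  pixel first (the protocol's µm diameters land on a 0.346 µm/px grid
  without a stated rounding rule; nearest-integer was chosen and a 10 µm
  disk at that resolution covers 613 pixels by exhaustive enumeration).
* Connected components for detection evaluation use 8-connectivity
  (unstated in the source protocol); true/false positives are counted per
  predicted component and false negatives per source dot, so two disks
  merged into one blob that both go unmatched count as two misses.
* Coordinates are 0-based (row, col) with origin top-left; annotations use
  (x = col, y = row). Pixel-in-polygon tests use the pixel centre and
  include boundary pixels, a deterministic, resolution-independent rule
  (how the source study rasterized pathologist ROIs is unstated).
* Patch tiling appends one flush-end offset when the extent minus patch
  size is not a multiple of the stride, so non-divisible extents are fully
  covered; the canonical 1000/400/200 tiling (16 patches per region) is
  unaffected.

## Validation protocol and problem sizes

The shipped tests validate, at sizes chosen to keep the default run in the
tens of seconds and the cohort-scale checks in a few minutes:

* oracle equivalence of the distance-transform partition on 100 random
  64 × 64 masks, plus partition/nesting/marker-swap invariants (the swap is
  exact off the tie set; tie pixels are verified to land on the positive
  side under both labelings);
* cell-count calibration: 1, 5 and 25 disjoint nominal-size disks recovered
  within 10% (pixelation is the only error source);
* parameter recovery on 50-case cohorts at the default conditions with a
  CD8 modulation of 0.2 carried by 93% of cases: the fraction of cases
  higher in K17-negative territory must fall in the binomial 95% interval
  of the carrier prevalence with a paired-t p below 1e-4, while a
  modulation-free cohort must give a centred fraction without the
  strong-effect signature. A single null cohort's p value is itself a
  uniform random variable, so "non-significant" is asserted as the absence
  of the effect-cohort signature (p > 1e-4) rather than an arbitrary
  α cut — exact type-I calibration is established separately by
* uniformity of the randomization-null p values (Kolmogorov–Smirnov
  p > 0.01 over 20 cases × 99 replicates under uniform placement).

`scripts/acceptance.R` re-runs the same computations from scratch at a
user-supplied seed and writes the resulting quantities as JSON.

## Known limitations

* Distances are straight-line; geodesic (obstacle-aware) distances are out
  of scope by design.
* The intratumoral denominator convention is a package choice (see above);
  scores are comparable within the package but not necessarily with tools
  that normalize by contact-shell area alone.
* Pixel-level counting cannot distinguish touching cells of one class;
  estimated counts are areas in disguise, and the 8/16 µm circles are
  population averages.
* Reported mean densities in the source literature mix /µm² and /mm²
  units; this package standardizes on cells/mm² and does not target those
  absolute figures.
* The randomization null treats cells as independent disks; it does not
  model cell–cell attraction or exclusion beyond the hard-core radius.
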