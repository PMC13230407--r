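---
title: "Forest archetypes: the classification system, its assessments, and the synthetic landscapes used to validate them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forest archetypes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestarch)
```

## The classification system

European forest landscapes can be summarised by a small number of
*archetypes*: characteristic combinations of naturalness, protection status
and wood-production intensity. `forestarch` implements a seven-class expert
rule system over five harmonized per-cell attributes on an equal-area grid
(100 m cells, 1 ha each):

* a **forest mask** (all other attributes are no-data off forest);
* **FAWS/FNAWS** — whether the forest is available for wood supply;
* **primary forest** presence, rasterized from polygon and point features;
* the **IUCN protection category** (Ia, Ib, II, III, IV, V, VI, or none),
  where Ia/Ib/II (strict nature reserve, wilderness area, national park) are
  treated as *strictly protected*;
* mean **wood production** in m³ ha⁻¹ yr⁻¹, resampled from a 1 km source.

The decision rules, applied in order to every forest cell:

1. primary forest **or** strictly protected → **A**, regardless of
   FAWS/FNAWS status — primary forests outside strict protection may well sit
   inside FAWS but remain without signs of human action;
2. otherwise FNAWS with protection III–VI → **B** (other protected forests);
3. otherwise FNAWS → **C** (unprotected forests outside wood supply);
4. otherwise (FAWS) by wood production: **D** below 1, **E** in [1, 2),
   **F** in [2, 4], **G** above 4 m³ ha⁻¹ yr⁻¹.

Protection categories III–VI never shield a FAWS cell from the intensity
path: a category-IV forest inside FAWS classifies as D–G by its wood
production, not as B. The rule paths are exhaustive and mutually exclusive,
which the test suite verifies property-style over the full discretized
attribute space.

### Interval conventions at the band edges

The published bands are printed as "< 1", "1–2", "2–4" and "> 4", which
leaves the shared endpoints ambiguous. "> 4" strictly read forces 4.0 into
F; applying the same left-closed reading to the interior edges puts 1.0 in E
and 2.0 in F. `forestarch` therefore fixes `D = [0, 1)`, `E = [1, 2)`,
`F = [2, 4]`, `G = (4, ∞)`. Because wood production is continuous, the
choice only matters for values exactly on an edge; it is documented in
`?threshold_set` and configurable.

FAWS cells with missing wood production are *unclassifiable*: they are
excluded from the map and counted (`n_unclassified`), mirroring how regions
without wood-production data are excluded from the real assessment rather
than imputed.

### 100 m to 1 km aggregation

The analysis raster is 100 m; presentation maps are 1 km.
`aggregate_majority()` takes the modal label of each 10×10 block, breaking
ties toward the lower rank (the more natural archetype) — a deterministic,
conservation-precautionary rule. Whether the published 1 km map was produced
this way or classified directly at 1 km is not stated in the source
material; both paths work here, since the classifier runs at either
resolution.

## What the synthetic generator emulates

No continental input data ship with the package. `generate_scene()` builds
seeded synthetic landscapes with the statistical structure the analysis
assumes, plus exact ground truth:

* **Spatial structure.** All categorical layers derive from white-noise
  fields smoothed with a Gaussian kernel and thresholded at quantiles — a
  neutral-landscape model producing large contiguous blobs rather than
  salt-and-pepper, as archetypes form large landscape patterns.
  `blob_scale_cells` (default 12) sets the correlation length; no empirical
  autocorrelation scale is available for the real inputs, so the default is
  simply a value that yields visibly blobby, multi-patch landscapes on grids
  of a few hundred cells.
* **Class fractions.** Defaults reproduce the continental accounting: 87%
  FAWS / 13% FNAWS, 4.4% primary or strictly protected (archetype A), 2.3%
  other-protected (B), 6.75% unprotected FNAWS (C), and the published
  within-FAWS split of D–G (42/21/26/11%). Realized fractions land within
  ±2 percentage points on grids of 512×512 and larger.
* **Wood production.** A lognormal moment-matched to mean 1.78 and
  SD 1.73 m³ ha⁻¹ yr⁻¹ (`meanlog` 0.244, `sdlog` 0.816). Its 95th percentile
  (≈4.9) matches the observed ≈5; its 5th percentile (≈0.33) does *not*
  reach the observed < 0.1 — a two-parameter lognormal cannot match both
  moments and both tail percentiles, and the moments win. The real field's
  left tail is heavier; conclusions that hinge on the abundance of
  near-zero-production cells should not lean on the generator. Cells in
  archetypes D–G draw from the lognormal truncated to their band, so the
  marginal field remains near-lognormal while staying consistent with the
  labels.
* **Vector inputs.** Primary forest and protected areas are emitted as
  vector features and re-rasterized through the same `rasterize_primary()` /
  `rasterize_protection()` code paths real data would take. A configurable
  share of primary features (default 10%) becomes point features carried as
  proportional circles, a sub-share of those (default 25%) with the
  patch-area attribute missing — mirroring the structure of the real
  primary-forest database, where a small minority of features are points and
  some lack the area attribute. Some strict components are additionally
  wrapped in an enclosing category-V polygon to exercise the
  most-protective-category precedence under nested designations.
* **Ground truth.** Labels are drawn first and layers constructed to match;
  after the vector features are rasterized back, the stored truth is
  recomputed from the final layers by the generator's own coding of the
  rules — deliberately separate from the classifier module, so the exact
  recovery test compares two independent implementations of the same rule
  table.

What passing tests on these scenes show is that the *pipeline* is correct:
rules, rasterization, accounting, patch delineation and statistics. They do
not validate the archetype concept against real European landscapes — the
generator has no topography, no country borders, no spatially varying
productivity drivers, and its blobs are isotropic.

## Assessment machinery

**Extent accounting.** `extent_table()` tabulates cells into areas per
region × archetype in thousands of km² (10⁶ ha cells = 10.0), with row and
column totals. `shares()` computes percentages against the grand total, a
row (region) total, or a column (archetype) total. For tables transcribed
from a publication the stored totals are the printed marginals, so share
arithmetic reproduces the printed percentages exactly, rounding included.

**Patch structure.** `label_patches()` delineates same-archetype components
under Moore (8-neighbour) connectivity; `build_patch_table()` drops
components of fewer than 3 cells ("more than two grid cells", i.e. > 2 ha at
1 ha per cell — the two phrasings agree), assigns each patch the region
holding the majority of its cells (ties to the patch's first cell in
row-major order), and `mps_matrix()` yields arithmetic mean patch sizes per
region × archetype. The component labeling is cross-checked against an
independent flood-fill oracle, exhaustively on all small two-class rasters
and on random larger ones.

**Group tests.** `one_way_anova()` is the classical fixed-effects
decomposition (fitted via `stats::aov`); `tukey_hsd()` computes all-pairs
adjusted p-values from the studentized range distribution with the
Tukey–Kramer standard error for unequal group sizes. `iterative_tukey()`
implements the stability rule used for patch sizes: 1000 iterations of Tukey
HSD on 1000 patches sampled per archetype (without replacement, capped at
group size), a pair being declared significant when p < 0.05 in at least 95%
of iterations. The transform is an explicit argument: natural log of patch
area for the patch analysis (the base only shifts means, never test
statistics), identity for wood production.

**Spatial thinning.** "Sampled to avoid spatial autocorrelation" is
operationalised as greedy distance thinning: candidates are visited in
seeded random order and accepted only if at least `min_separation_m` (default
2000 m, two 1 km wood-production cells) from every accepted cell of the same
group. The guarantee is assertable — every returned sample passes an
exhaustive pairwise distance check — and `min_separation_m = 0` recovers
plain sampling without replacement. The source material states the goal but
not the method; greedy thinning is the simplest scheme with a provable
separation property.

**Gradient slices.** `slice_assessment()` cuts the projected plane into
half-open bands (default: nine 500 km latitudinal slices from
1 000 000 m N, whose edges correspond to 32.0° N and 72.7° N under the
European Lambert azimuthal equal-area projection), restricted to archetypes
D–G. Cells exactly on a slice edge belong to the upper slice. The
ellipsoidal LAEA forward/inverse (GRS80, latitude of origin 52° N, central
meridian 10° E, false easting 4 321 000 m, false northing 3 210 000 m) is
implemented in the package via the authalic-latitude series; the inverse
reproduces both graticule anchors at one-decimal precision and round-trips
the forward map to 10⁻⁷ degrees.

**Sensitivity and benchmarking.** `sensitivity_sweep()` perturbs each
threshold independently (defaults ±10% and ±25% — the original supplementary
design is not public, so the magnitudes are parameterized) and re-bands only
the FAWS intensity path; A–C are threshold-independent by construction.
`benchmark_agreement()` compares stratum-wise compositions with the
proportion-overlap statistic Σ min(p, q) — 100% iff identical, 0% iff
disjoint — area-weighted across strata; the default archetype grouping
{A,B} / {C,D} / {E,F,G} onto reserve / extensive / intensive classes is
configurable because the reference accounting's exact mapping is unknown.

## Numerical choices and degenerate inputs

* Cell membership is by cell-centre coverage, half-open cells
  `[x, x+s) × (y−s, y]`; rasterization is order-independent except where the
  most-protective precedence resolves overlaps.
* Point features become discs of radius `sqrt(a·10⁴/π)` m; the discretized
  disc's cell count converges to the attributed area (≤5% error at radii
  ≥ 10 cells). Missing areas impute the regional mean of attributed points,
  falling back to the global mean; no attributed points at all is an error.
* Wood-production resampling is nearest-neighbour (containing cell):
  the source values are administratively downscaled means, and interpolation
  would invent sub-cell detail.
* ANOVA with zero variance everywhere raises a degenerate-input error;
  groups with fewer than two members are excluded (with a warning) from the
  iterative Tukey procedure.
* All randomness flows through explicit integer seeds; scenes, samples and
  pipeline runs are bit-reproducible for a fixed configuration.

## Problem sizes

The bundled tests validate exact ground-truth recovery on ten 512×512 scenes
(~140 000 forest cells each), fraction calibration at 512×512, patch-oracle
equivalence exhaustively up to 9-cell rasters plus randomized 4×4, 8×8 and
50×50 cases, and null calibration of the tests over 500 replicates; the
end-to-end pipeline example runs on 96×96 scenes. These sizes make the whole
suite run in a few minutes while leaving every statistical check at full
strength; nothing in the implementation is specific to them, and the
generator scales to arbitrarily large grids.

## Known limitations

* The generator's lognormal left tail is lighter than the real
  wood-production field's (see above).
* Regions are Voronoi cells, so region boundaries are straight; patch/region
  majority assignment is exercised, but not the convoluted boundaries of
  real biogeographical regions.
* Agreement benchmarking implements the comparison framework, not the
  published reference database; published agreement percentages are not
  reproducible at desk scale and are not targeted by any test.
* No reprojection: all inputs must arrive in the analysis CRS. Topology
  repair of invalid polygons is out of scope.
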