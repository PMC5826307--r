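---
title: "From airborne laser points to tree architecture models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From airborne laser points to tree architecture models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Airborne laser scanning (ALS) samples forest canopies at around 1-50
points/m². That is enough to see a tree's silhouette but far too sparse to
reconstruct branches. Botanists, however, condensed the diversity of tree
forms into a small catalogue of *architecture models* — qualitative
archetypes of trunk/branch organization and growth rhythm (Hallé's scheme).
Four of them cover the common boreal broadleaf/conifer habit space:

* **Massart** — plagiotropic (horizontal) main branches in whorls, rhythmic
  growth: tiered, conical crowns.
* **Rauh** — orthotropic branches morphogenetically equivalent to the
  trunk, rhythmic growth: clustered foliage blocks high in the crown.
* **Roux** — plagiotropic, monopodial, non-phyllomorphic branching with
  continuous growth: evenly layered crowns.
* **Attim** — orthotropic branches equivalent to the trunk with more or
  less continuous growth: dense columnar fill.

`crownarch` operationalizes the link between sparse ALS point clouds and
these archetypes: it derives structural feature parameters per tree,
classifies species with a leave-one-out support vector machine over
exhaustive feature subsets, averages a feature pair per classified species,
and assigns the nearest architecture-model prototype, attaching the
model's qualitative growth-habit record.

## Geometric scaffolding

Every feature rests on a per-tree `crown_frame`:

* **Stem axis.** The first principal component of the *extracted stem
  points*: points in the lowest 25% of the height range within 1 m
  (horizontally) of their horizontal median. A blanket PCA of the whole
  lower cloud fails for deep-crowned trees, where foliage dominates the
  lower points — hence the extraction step. The PCA estimate is accepted
  only if the extraction looks like a stem: at least 10 points spanning at
  least 2 m vertically with a root-mean-square spread of at most 0.35 m
  around the fitted line, tilted at most 30° from vertical. Otherwise the
  axis falls back to the vertical through the horizontal centroid, with a
  warning. These gates were added after observing that stubby or spurious
  extractions (e.g. an 0.8 m stem fragment, or a handful of near-axis
  noise returns) pass a tilt-only check while distorting every
  radius-dependent feature downstream.
* **Crown base.** The point-height profile in 0.5 m bins, smoothed with a
  3-bin moving average, crossed upward against a threshold of 5% of the
  smoothed maximum (absolute floor: 2 points), where the crossing must be
  *sustained* for three consecutive bins. Flat crown profiles can push 5%
  of the maximum below a single point; without the floor and the
  sustained-crossing requirement, lone stem returns truncate or extend the
  crown by metres and make the detection unstable against point density.
  A user-supplied base always overrides detection.
* **Voxels, sectors, layers.** Cubic voxels (default 0.5 m — half the 1 m
  super-voxel used for the clustering feature, fine enough to resolve
  ~10 points/m² data) anchored at the crown's minimum corner with
  half-open `[min, max)` intervals; 8 azimuthal sectors around the stem
  axis, sector 1 starting at geographic east, counter-clockwise; and 8
  equal-thickness vertical layers. All three conventions are arbitrary but
  fixed, so that results are reproducible across runs and implementations.
* **Extent.** Crown length `Lc`, crown radius `Rc` (maximum horizontal
  point distance from the axis — note this is a max statistic, see
  *Limitations*), and projected crown area `A_base` (2-D convex hull).

Heights are measured above the crown base wherever they are normalized by
`Lc`, so those ratios land in `[0, 1]` regardless of terrain.

## Crown-internal (CI) parameters P1-P13

Thirteen dimensionless descriptors of branch/leaf organization: sector-wise
relative centroid heights and radii and their spreads (P1, P2, P5, P6,
P13 = P5/P6), the lower-third footprint ratio (P3), the largest point
fraction in any 1 m super-voxel (P4, leaf clustering), stem-space voxel
occupancy (P7: lower third of the crown within `Rc/2` of the axis),
whole-crown centroid height (P8), layer-count spread and adjacent-layer
difference ratio (P9, P10), the alpha-complex to convex-hull volume ratio
(P11, alpha 0.5 m), and the opposite-to-adjacent sector-profile correlation
ratio (P12, branching symmetry).

Numerical conventions, fixed and deliberate:

* standard deviations are population (n-denominator) throughout;
* empty sectors are excluded from the P1/P2 means (and logged);
* a zero-variance sector profile contributes correlation 0 to P12;
* degenerate denominators (P6 below 1e-9 for P13, a zero adjacent sum for
  P12) yield a sentinel value 0 with a warning rather than `NaN` — a
  perfectly regular crown should not crash a batch run;
* P11's volumes come from a gift-wrapping Delaunay tetrahedralization
  (compiled code) evaluated with exact-sum signed volumes; cospherical or
  coplanar degeneracies are resolved by a deterministic internal jitter of
  one part in 10^6, and coordinates never leave double precision.

## Tree-external (TE) parameters

Tree height `Ht`, crown ratio `LcHt`, area-equivalent crown diameter
`D_EA = 2 sqrt(A_base / pi)` (the definition "diameter of the circle with
area equal to the crown cover" forces the `1/pi`; a formula without it is
not a diameter), the Gaussian spread `Alpha` of the vertical crown profile,
`LcD_EA`, two density-peak descriptors, the mean occupied-voxel height
`Gc`, and two grid-coverage fractions (`P_L` from the two side projections,
`LAI_proj` from the vertical projection; both are coverage fractions of
the projected hull, clamped at 1 because boundary-straddling cells
otherwise overshoot slightly — `LAI_proj` is *not* a radiative-transfer
leaf area index, hence its name).

`Alpha` is fitted by least squares as `exp(-(h - u)^2 / (2 a^2))` against
the 40-bin crown profile normalized to maximum 1 (amplitude fixed;
location and spread free), Levenberg-Marquardt with a Gauss-Newton polish;
if the optimizer fails, the profile's second moment is returned with a
warning. The density-peak descriptors are exposed as
`llls_lhls_proxy` and `ls_lcs_proxy` deliberately: the quantities they
estimate are identified here with the lowest/highest local maxima of the
smoothed vertical density profile and with the maximum-density bin — a
definition this package fixes rather than inherits, so the proxy names
keep that visible in output headers.

## Species classification

The MANOVA gate (Wilks' lambda) reports whether the classes separate at
all on the chosen columns; it never blocks the pipeline, and a singular
within-class covariance triggers a ridge-regularized (1e-8) Wilks
statistic with Rao's F approximation instead of an error.

Classification is a LIBSVM C-classifier (radial kernel, `C = 1`,
`gamma = 1/n_features`) in leave-one-out cross-validation. Feature columns
are z-score standardized *per fold* using only the training trees — the
paper-level description leaves standardization unstated, but anything else
leaks the held-out tree into the scaler. Training rows are sorted by tree
identifier internally, making the whole procedure invariant to the row
order of the input table. Hyperparameters are fixed rather than tuned per
subset: the exhaustive search evaluates up to 8191 subsets, and per-subset
tuning would both explode the runtime and invalidate the comparison
between subsets.

The subset search enumerates every unordered subset of each requested
size (counts are exactly `choose(pool, k)`; for 13 columns:
13, 78, 286, 715, 1287, 1716, 1716, 1287, 715, 286, 78, 13, 1), breaking
accuracy ties toward the smaller subset and then lexicographically —
smaller subsets generalize better at equal observed accuracy, and the rule
makes the winner unique and reproducible. Accuracy metrics are per-class
recall and precision, overall accuracy, and Cohen's kappa.

## Architecture-model identification

Per classified species, the mean of a feature pair — by default (P4, P7),
clustering vs stem-space occupancy — is compared against four prototype
centres shipped in an editable YAML knowledge base. The default rule is
nearest centre after per-axis min-max scaling over the prototypes (so the
assignment is invariant to affine rescaling of either feature), because
the four models do not fill four quadrants: three of them share "low P7"
and only differ in P4 level. The quadrant rule, with configurable cut
lines and a quadrant-to-model map, remains available; a centre exactly on
a cut line tie-breaks to the lower quadrant with a warning.

The prototype centres are expert inputs, not fitted constants: they encode
the qualitative low/moderate/high signatures of the four models on the
scale this feature pair takes for ~10 points/m² ALS crowns (anchored, in
this package, to what the bundled simulator's archetypes realize:
Massart (0.029, 0.010), Rauh (0.120, 0.031), Roux (0.035, 0.091),
Attim (0.014, 0.164)). Users working with other sensors, densities or
forests are expected to edit the file. The knowledge base also carries
*two* readings of the growth-habit texts — one indexed by model, one by
species — because the reference literature pairs some species with habit
rows that differ from their model's own description; the package reports
both and does not reconcile them.

Post-classification feature distributions are summarized per species by
Gaussian maximum likelihood (mean and population standard deviation) on
the predicted-label group (DP) and the true-label group (GT), with
relative divergences `(GT - DP) / GT * 100` for both moments — the sign
convention is fixed here because mixed conventions make tables ambiguous.

## The synthetic stand generator

No reference point-cloud data ship with the package; every pipeline stage
is exercised against a simulator whose defaults describe a 40-tree boreal
stand (9 Norway spruce PA, 14 Scots pine PS, 7 European aspen PT, 10
English oak QR), with species-wise height and crown-length ranges from the
descriptive statistics of such a stand (e.g. PA heights 17.60-28.38 m),
~10 points/m² areal density, 0.15 m positional noise, and 2% sparse stem
returns. Each species realizes one archetype recipe:

* `massart_tiered` — outer-shell annuli (0.80-1.00 of the local radius) on
  regularly spaced whorl tiers inside a cone;
* `rauh_clustered` — a few strongly unequal, vertically elongated foliage
  clusters in the upper 50-90% of the crown over a sparse full-crown fill;
* `roux_layered` — evenly spaced branch layers at regular azimuths with
  foliage strung along the branches (the regularity is the point: this is
  what monopodial continuous branching looks like to a profile
  correlation);
* `attim_columnar` — near-uniform columnar fill with an inner core and a
  handful of vertical sub-columns.

The recipes are structural caricatures guided by the models' qualitative
descriptions — a test harness, not a claim about real species. What they
deliberately do *not* emulate: occlusion and multi-return physics, beam
divergence, understory, terrain, crown asymmetry from competition, and the
within-species morphological variance of real forests. Passing the
pipeline-closure checks on this generator therefore demonstrates internal
consistency of the feature definitions, the classifier wiring and the
prototype logic — not field-level accuracy, which can only be assessed
against real reference crowns.

Generator parameters were frozen while designing the recipes (against
stand simulations with seeds 1-6) and are study conditions, not dials; the
knowledge-base prototypes above were anchored once to the same frozen
recipes.

## Numerical choices and problem sizes

* Voxel size 0.5 m, super-voxel 1 m, 8 sectors, 8 layers, 40 profile bins,
  alpha radius 0.5 m, projection cells 0.5 m — all configurable.
* The Delaunay backend is exact against a brute-force empty-circumsphere
  enumeration on clouds in general position and recovers degenerate hulls
  (e.g. the corners of a cube) exactly via signed-volume summation.
* The test suite runs stands of 12-40 trees and property checks at up to
  1000 random clouds; the bundled acceptance script simulates five 40-tree
  stands. These sizes make the full pipeline statistics stable while
  keeping a complete run in the low minutes on one core.

## Known limitations

* `Rc` is a maximum statistic: at ALS densities its sampling noise is a
  few decimetres, so P2 (normalized by `Rc`) moves by a few hundredths
  between resamplings of the same crown. Density-doubling stability holds
  on average (< 0.05 for P1, P2, P8) but individual draws can reach ~0.1.
* P12 is a ratio of correlation sums; for crowns with weakly structured
  sector profiles its denominator approaches zero and the parameter
  becomes noisy (the sentinel handles the exact-zero case).
* Crown-base detection assumes the crown is the densest contiguous part of
  the profile; heavily occluded real-world stems or dense understory
  violate that and call for the manual override.
* The quadrant identification rule cannot express three models sharing
  "low P7"; it is provided for completeness, nearest-centre is the
  default.
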