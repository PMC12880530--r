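---
title: "Quantifying cerebral amyloid angiopathy along the arterial tree: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cerebral amyloid angiopathy along the arterial tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caa3d)
```

## The scientific problem

Cerebral amyloid angiopathy (CAA) is the deposition of amyloid-beta
(A&beta;) in the walls of cortical arteries and arterioles. Light-sheet
imaging of cleared tissue blocks, double-stained for smooth-muscle actin
(SMA, delineating the vessel media) and A&beta;, makes it possible to
follow deposition along *anatomically continuous* arterial trees — from
the leptomeningeal artery (LMA) on the brain surface, through the
cortical entry point, down the branching hierarchy — instead of scoring
isolated vessel cross-sections.

`caa3d` implements that surface-to-depth quantification as a tested
pipeline:

1. **Topology** — read traced skeletons (SWC), find each vascular unit's
   parenchymal entry point, and label segments by branching depth:
   `LMA`, `D0` (entry to first branch), `D0-D1` (the bifurcation
   region), `D1`, … up to `D6`, pooling anything deeper as `DEEPER`.
2. **Classification** — score each segment A&beta;-positive/negative and
   SMA-present/lost, roll statuses up to the unit, and compute the
   *vascular amyloid load* of a sample (percent positive units; low
   < 40 %, moderate 40–60 % closed, high > 60 %) and per-segment load
   rates among positive units.
3. **Morphometry** — D0 external diameter as twice the median D0 radius
   (median, not mean: mural A&beta; bulges are outliers).
4. **Plaques** — detect parenchymal senile plaques as spots, discard
   dual-channel autofluorescence artifacts, count spots whose center
   lies 10–100 µm (inclusive) from a unit's filament, and normalize by
   filament length (n/µm); flag dyshoric change (linear perivascular
   deposition) per segment.
5. **Statistics** — quartiles, Mann–Whitney U, Kruskal–Wallis, and
   Steel–Dwass all-pairs comparisons.

Because no imaging data ship with this package, a first-class
synthetic cohort generator
(`simulate_cohort()`) produces ground-truth vascular units, deposition
statuses, plaque point patterns and (optionally) rasterized two-channel
volumes with the statistical structure the analysis assumes. Every
downstream stage is tested end to end against that ground truth.

## The generative model

### Geometry

A vascular unit grows from a short LMA stub above the surface plane
(`z = 0`; depth increases with `z`), crosses the plane, and extends by
downward-biased runs that bifurcate after each run with probability
`branch_prob * branch_decay^depth`. The depth decay reflects that
penetrating arterioles branch almost surely near the surface and rarely
at depth; with the defaults (0.95, 0.6) the median filament length is
about 1.3–1.5 mm with quartiles near 0.9 and 1.9 mm, matching the
scale reported for traced human arterial units (median 1.55 mm,
interquartile 1.02–2.31 mm). Child diameters taper by `taper` (0.8)
per generation with a hard floor at `diameter_floor_um = 8` — the
arteriole inclusion rule — and a cap at `diameter_cap_um = 60`
(arterioles; larger trunks are outside the measured range). Root (D0)
diameters are lognormal with medians 36.73 µm (A&beta;-positive units)
and 25.94 µm (negative units) and `diameter_sdlog = 0.3`, which
reproduces the published interquartile ranges. Branch angles, step
sizes and run lengths are invented (no branching statistics are
published) and are exposed as parameters.

A designated fraction `p_penetrate_wm` of units extends past the
cortex/white-matter boundary; designated units that stall are extended
by an unbranched continuation so the designation is exact.

### Deposition front

A unit is A&beta;-positive with probability `p_unit_abeta` (default
1104/1639). For a positive unit the LMA is positive with probability
`p_lma_abeta = 0.962`, independently of the cortical front (the
published LMA rate, 96.2 %, is *below* the D0 rate, 99.5 %, so the LMA
cannot simply inherit the front). A front depth `F` is drawn so that
`P(F >= d) = front_reach_probs[d]`; all depth segments with `d <= F`
are positive, and a bifurcation segment `Dd-Dd+1` follows depth `d`.
This survival-function parameterization — rather than independent
per-segment Bernoulli draws — is what produces the observed
anatomically contiguous prefix pattern.

The default profile is the published per-segment load profile (99.5,
45.8, 19.8, 10.0, 4.5, 6.3, 0 percent for D0…D6) with one adjustment:
the published D5 value exceeds D4 and therefore cannot be a survival
probability, so the default applies a running minimum (D5 = 4.5 %).
Non-monotone inputs raise a validation error unless `strict = FALSE`,
in which case they are monotonized the same way.

Rare variants: with probability `p_skip` (11/1104) one deep segment is
positive while intermediate cortical segments are negative, keeping the
LMA or D0 anchor positive (the published skip pattern); with
probability `p_wm_confined` deposits are confined to white-matter
segments plus the superficial anchor. Within a positive segment the
deposit occupies a contiguous run of `sporadic_fill = 0.6` of its
length (at least 12 µm) at a random offset; the published account notes
sporadic within-segment deposition without quantifying it.

### Smooth-muscle loss

Only positive units lose SMA (probability `p_sma_loss = 547/1104`).
The most superficial lost segment is drawn from `sma_onset_dist` over
{LMA, D0, D1, deeper}, restricted to the unit's positive labels, and
loss extends contiguously from the onset through the deepest positive
segment — so the lost set is nested in the positive set by
construction, as observed. The default onset weights (0.65, 0.30,
0.04, 0.01) reproduce the published per-sample onset medians (about
40 % LMA, 21 % D0, 0 % at D1 and deeper) after accounting for the
~50 % of positive units without loss.

### Plaques, thinning, dyshoric sleeves

Parenchymal plaques are a homogeneous Poisson process of intensity
`plaque_lambda0` per µm³ of cortex, thinned: candidates within 100 µm
of any positive unit's filament are retained with probability
`plaque_thinning_theta` (0.85), emulating perivascular plaque
rarefaction around amyloid-laden arteries. Two deliberate departures
from a bare Poisson process:

* **Hard-core clearance.** Plaques are parenchymal, never intramural: a
  candidate is rejected within `radius + diameter_cap_um/2 + 13` µm of
  any filament. The clearance is *uniform across units* — deliberately
  not a function of the local vessel radius — because positive units
  are systematically thicker, and a radius-linked clearance would act
  as a diameter covariate that mimics thinning even at `theta = 1`.
  With the uniform rule, `theta = 1` is an exact null (verified: no
  significant positive/negative density difference in ≥ 90 % of
  replicate cohorts).
* **Calibration.** `plaque_lambda0 = 3.7e-6` is set so that the
  generated per-unit band density matches the published median
  (≈ 0.019–0.020 n/µm, ≈ 30 spots on a median filament). The naive
  estimate from band volume alone (≈ 6e-7) lands three-fold low once
  clearance, surface truncation and thinning are accounted for.

Each positive cortical unit with a positive D0 segment develops
dyshoric change with probability `p_dyshoric_unit = 0.127`; the sleeve
sits on D0 with probability `dyshoric_d0_share = 0.915`, otherwise
uniformly on another positive cortical segment, and occupies an annulus
5–20 µm outside the wall over a lognormal longitudinal extent (median
80 µm). Requiring a positive D0 for eligibility keeps the placement
share exact: without it, the few units whose short trunk run is
entirely consumed by the first bifurcation region would silently
re-route their D0 draws and bias the share.

### Rasterization

`rasterize()` renders a sample at `voxel_size_um` (default 2 µm; the
sampling of the source imaging is not published): SMA as solid tubes
where smooth muscle is present, wall deposits as tubes thickened by
`wall_thickness_um = 4` over each deposit run, plaques as solid spheres
(spots are spheres by definition), dyshoric sleeves as
thickened tubes over their extent, and dual-channel autofluorescent
puncta at equal intensity in both channels — the lipofuscin-like
artifacts that motivate the ratio filter. A Gaussian PSF
(`psf_sigma_um = 1.5`) and optional Poisson shot / Gaussian read noise
follow; output is 16-bit. Two rendering details matter for
consistency:

* Wall deposits and sleeves are painted as *capped cylinder chains*,
  not sphere chains: a sphere chain spills roughly one radius of wall
  signal past the end of a deposit run, which converts the neighboring
  (truth-negative) segment into a measured-positive one at every
  deposition-front boundary.
* The field of view extends one LMA length above the surface plane
  (negative-z origin recorded in the volume), so leptomeningeal
  segments are imaged as they are in the cleared blocks.

## Analysis choices

**Depth labeling.** The bifurcation segment `Dd-Dd+1` is the arc within
`bif_radius_factor = 2` local radii of the branch node (the published
definitions name the segment but not its extent; a radius-scaled extent
keeps bifurcation regions proportionate). Trifurcations count as a
single depth increment. Along every root-to-leaf path the label order
is non-decreasing, and labeled segment lengths below the entry
partition the intraparenchymal skeleton exactly.

**Segment classification.** The A&beta; classifier samples an annulus
`wall_band = c(0, 6)` µm beyond the local radius at ≤ 2 µm centerline
steps (8 directions × 3 radial depths, per-step maximum) and calls a
segment positive iff some contiguous above-threshold run is at least
`run_min_um = 10`. SMA presence requires the longest below-threshold
centerline run to be at most `gap_max_um = 20` (inclusive). One
extension beyond the plain annulus rule: because the traced filaments
of *all* units are inputs, annulus samples lying closer
(radius-normalized, with a 4 µm blur margin) to another segment's wall
than to the classified segment's wall are discounted — wall signal is
attributed to the nearest filament, as a human rater does implicitly.
Parents, children and siblings of the segment are exempt (they meet it
at a junction and share its status under the front model). Without
this attribution, deposits on a thick trunk are scored onto curving
descendants and the ground-truth and image pipelines cannot agree.

**Load classes.** "40 to 60 %" is read as the closed interval: a
fraction of exactly 0.40 or 0.60 classifies as moderate.

**Per-segment rates.** The denominator for label L is the number of
positive units *possessing* L (an alternative all-positive-units
denominator is exposed via `denominator = "all_positive"`); the
published figure does not state its denominators.

**Spot detection.** Laplacian-of-Gaussian at scale
`sigma = diameter / (2 sqrt 3)` with the published spot diameter of
50 µm; local maxima are kept above a quality threshold (the smoothed
amyloid intensity at the center — the instrument-specific published
"quality 30 to 50" does not transfer, so `quality_min` is calibrated on
the synthetic fixtures) and greedily non-maximum-suppressed at half the
spot diameter, so blobs closer than 25 µm merge. The published
deep-learning plaque classifier is deliberately replaced by two
reproducible rules: the dual-channel ratio filter (artifact iff SMA
intensity ≥ 0.8 × quality at the center) and the 10 µm inner band
bound, which removes on-wall deposits.

**Distances and densities.** Spot-to-filament distance is the minimum
clamped-projection distance from the spot *center* to the unit's
polylines; the 10–100 µm band is inclusive at both bounds.
White-matter-penetrating units and units flagged for perivascular
artifacts are excluded from density analysis. Density is spots per µm
of filament; it is invariant to re-parameterizing the centerline.

**Dyshoric flagging.** A segment is flagged iff perivascular amyloid in
the annulus (excluding voxels explained by retained spots) covers a
contiguous run of at least `length_min_um = 50` with at least
`coverage_min = 0.5` of circumferential samples above threshold —
isolated spherical blobs fail the linear-extent requirement. The inner
sampling offset sits 4 µm beyond the annulus bound to keep a
voxel-rounding margin above the wall deposit. Both constants are
invented and config-exposed. At cohort scale the package also
attributes *truth* sleeves geometrically (three probe points offset
into the annulus, majority vote over nearest segments), which recovers
the placement distribution without rasterizing thousands of units.

**Statistics.** Quartiles use linear interpolation between order
statistics (the original analysis software's convention is not
published). Mann–Whitney U is exact by enumeration when both groups
have at most 8 observations without ties, otherwise the tie-corrected
normal approximation with continuity correction. Kruskal–Wallis uses
the tie-corrected H against chi-square. Steel–Dwass re-ranks each pair
separately and refers the tie-corrected standardized statistic times
sqrt 2 to the studentized range distribution with k groups and infinite
degrees of freedom — the standard asymptotic form; exact small-sample
tables are out of scope, and numerical parity with any particular
commercial implementation is not claimed. At k = 2 it reduces to the
two-sided normal-approximation Mann–Whitney test (without continuity
correction) to within 1e-6.

## Problem sizes and determinism

All randomness flows from a single seed per cohort; identical
parameters give byte-identical SWC, tables and volumes. The test suite
and the acceptance script run at desk scale, chosen as the sizes at
which the binomial/Poisson error bands become decisive rather than the
published specimen sizes: 2,100 positive units for the
deposition-front round-trip (three-binomial-SD bands on the D0 and D1
rates), 1,100 units for the dyshoric share, 10,000 light units for the
contiguity invariant, 330 cortical units on a sparse 4.5 × 4.5 mm slab
for the thinning contrast (the sparse layout keeps neighboring units'
100 µm bands from overlapping into each other's thinning halos), 20
replicate cohorts for the `theta = 1` null, and a 60-unit fixture with
a 300 × 300 × 146 voxel raster for the truth-versus-image equivalence
check.

## What the synthetic cohort does and does not establish

The generator emulates the *statistical structure* the analysis
assumes: contiguous surface-to-depth deposition with rare skips, SMA
loss nested in deposition, diameter differences by status, plaque
thinning near positive vessels, D0-dominant dyshoric change, and
dual-channel puncta artifacts. Passing tests therefore demonstrate
that the pipeline recovers known truth under those assumptions — they
do not validate the assumptions against real tissue, and several
realities are deliberately absent: curved cortical surfaces, veins and
capillaries, spatially varying plaque intensity, anisotropic PSFs,
tracing errors in the input skeletons, and the intensity heterogeneity
of diffuse versus neuritic plaques. Published specimen-dependent
quantities (per-segment rates on real vessels, diameter medians,
density medians, p-values) are generator calibrations here, not
measurements; only their recovery is evidence.

Two published figures are knowingly inconsistent and are not targeted:
the total filament length (2.36e5 µm) is about tenfold smaller than
the median unit length times the unit count, and the D5 load rate
exceeds D4 (see the front-profile monotonization above).

## Reproducing the analysis

The `analysis/` scripts build a 12-sample cohort (six donors, frontal
and occipital each, loads spanning low to high, three donors per CAA
type) and write all tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_label.R
Rscript analysis/03_classify.R
Rscript analysis/04_plaques.R
Rscript analysis/05_report.R
```

`scripts/acceptance.R` recomputes the headline quantities (load
percentages and tallies from the published counts, the D0/D1
round-trip rates, the dyshoric D0 share) from scratch at a given seed.
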