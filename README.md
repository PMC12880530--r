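# caa3d — surface-to-depth quantification of cerebral amyloid angiopathy

Cerebral amyloid angiopathy (CAA) is the deposition of amyloid-β (Aβ) in
the walls of cortical arteries and arterioles. In 3D light-sheet volumes
of cleared tissue double-stained for smooth-muscle actin (SMA) and Aβ,
deposition can be followed along *anatomically continuous* arterial
trees — "vascular units" branching from a common leptomeningeal artery
(LMA) — rather than scored on isolated cross-sections. `caa3d` is an R
package for neuropathology/image-analysis groups doing exactly that
quantification, plus a synthetic cohort generator so every stage of the
pipeline is testable end to end without imaging data.

## What it computes

Given traced skeletons (SWC) and two-channel volumes (or ground-truth
tables from the generator):

* **Depth labeling.** Each unit's parenchymal entry point is found on
  the surface plane and segments are labeled by branching order:
  `LMA`, `D0` (entry → first branch), `D0-D1` (bifurcation region),
  `D1`, …, `D6`, `DEEPER`. Superficiality order
  LMA < D0 < D0-D1 < D1 < … < DEEPER.
* **Segment classification.** Aβ-positive iff a contiguous
  above-threshold run ≥ 10 µm is present in an annulus 0–6 µm outside
  the wall; SMA present iff the longest centerline signal gap ≤ 20 µm.
  A unit is positive iff any segment (including the LMA) is.
* **Vascular Aβ load.** For a sample with *n⁺* positive of *n* units,
  load = *n⁺/n*, classed low (< 40 %), moderate (40–60 %, closed) or
  high (> 60 %); per-segment load rates among positive units are
  `P(segment L positive | unit positive, unit possesses L)`.
* **Morphometry.** D0 external diameter = 2 × median D0 radius, with
  radii measured from the SMA channel by a 3D Euclidean distance
  transform at the centerline.
* **Perivascular plaques.** Spots detected by scale-matched
  Laplacian-of-Gaussian (diameter 50 µm), dual-channel autofluorescence
  artifacts removed by an SMA/Aβ ratio rule, counted in the inclusive
  10–100 µm center-to-filament band, normalized per µm of filament.
* **Dyshoric change.** Linear perivascular deposition flagged per
  segment (contiguous run ≥ 50 µm with ≥ 50 % circumferential
  coverage in the 5–20 µm annulus, spots discounted).
* **Statistics.** Quartiles (linear interpolation), two-sided
  Mann–Whitney U (exact at n ≤ 8 without ties, tie-corrected normal
  approximation otherwise), tie-corrected Kruskal–Wallis, and
  Steel–Dwass all-pairs comparisons with p = P(Q₍k,∞₎ ≥ |z|√2) from
  the studentized-range distribution.

The generator (`cohort_params()` + `simulate_cohort()`) encodes the
conditions the analysis assumes: a deposition front with survival function
P(front ≥ d) over depths (default the published per-segment profile),
independent LMA positivity (96.2 %), rare skip and white-matter-confined
variants, SMA loss nested in deposition, D0 diameters lognormal with
medians 36.73/25.94 µm by status, Poisson plaques thinned near positive
vessels, D0-dominant dyshoric sleeves, and dual-channel puncta
artifacts. See the methods vignette (`vignettes/caa3d-methods.Rmd`)
for the model, its calibrations and its limitations.

## Worked example

```r
library(caa3d)

p <- cohort_params(n_units = 90, p_unit_abeta = 0.70, seed = 7005L,
                   slab_dims_um = c(2000, 2000, 1200))
s <- simulate_cohort(p)
vascular_load(Filter(function(u) is.na(u$excluded_reason), s$units))
```

```
<load_summary> 62/90 positive (68.9%) -> high
# A tibble: 12 x 4
   label n_possessing n_with_positive   rate
   <chr>        <int>           <int>  <dbl>
 1 LMA             62              59 0.952
 2 D0              62              62 1
 3 D0-D1           62              62 1
 4 D1              62              35 0.565
...
```

62 of 90 units are Aβ-positive (68.9 %, class high); the per-segment
rates fall steeply from D0 (100 %) to D1 (57 %), the surface-to-depth
gradient the pipeline is built to measure.

The `analysis/` scripts run the full workflow on a
12-sample synthetic cohort (six donors × frontal/occipital, loads
spanning low to high, three donors per CAA type), writing all tables
under `results/`:

```sh
Rscript analysis/01_simulate.R   # cohort + truth tables + SWC
Rscript analysis/02_label.R      # SWC -> entry points -> depth labels (QC)
Rscript analysis/03_classify.R   # per-sample loads + per-segment rates
Rscript analysis/04_plaques.R    # band densities + dyshoric attribution
Rscript analysis/05_report.R     # grouped quartiles + MW/KW/Steel-Dwass
```

On the default cohort this prints, among others: a class tally of
2 low / 5 moderate / 5 high across the 12 samples; a pooled segment
profile of 96.1 % (LMA), 99.7 % (D0), 98.5 % (D0-D1), 45.0 % (D1),
21.0 % (D2) falling to 0 % by D5; pooled perivascular densities of
0.0353 (Aβ⁺) vs 0.0382 (Aβ⁻) n/µm with Mann–Whitney p = 1.3 × 10⁻⁴ —
the plaque-rarefaction signature of the thinning model — and a
dyshoric D0 share of 98 % of 49 affected segments.

## Layout

```
R/                  package code (generator, topology, classification,
                    plaques, statistics, pipeline)
src/                compiled volume ops (EDT, Gaussian blur, stamping,
                    local maxima, batch point-segment distances)
analysis/           numbered analysis drivers (see above)
scripts/            acceptance script
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette
```
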