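---
title: "Quantifying and mapping forest understory density from lidar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and mapping forest understory density from lidar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(understoRy)
```

## The problem

The understory — shrubs, regeneration, and small trees beneath the
dominant canopy — matters for biodiversity, fuel loads, and forest
dynamics, but it is rarely inventoried: it is tedious to measure in the
field and invisible to most optical remote sensing. Two lidar
viewpoints complement each other here. A hand-held terrestrial laser
scanner (TLS) walked through a plot sees the understory in detail from
below but only covers a fraction of a hectare. An airborne laser
scanner (ALS) covers whole landscapes from above, but its pulses must
penetrate the canopy before they sample the understory.

`understoRy` implements the full chain that links the two: a
voxel-based understory density index from TLS plot scans, a set of
plot-level ALS metrics, correlation-screened linear models calibrated
on the plots and evaluated by leave-one-out cross-validation, and
wall-to-wall application of those models on a prediction grid. A
synthetic scene simulator with exact ground truth closes the loop so
every stage is testable without field data.

## Plant Density Index from TLS

A height-normalized plot cloud is clipped to a parallelepiped: a 27 m
square base centred on the plot and heights 0.5–15.5 m above ground
(the floor avoids ground vegetation and terrain residue; the ceiling
reflects the working range of hand-held scanners). The box is divided
into 0.5 × 0.5 × 0.25 m voxels — 54 × 54 × 60 = 174,960 of them — and
a voxel is *vegetated* when it contains at least five points. The
occupancy threshold doubles as a filter against the "ghost points" that
phase-shift scanners produce near object edges.

The Plant Density Index (PDI) of a height stratum is the fraction of
vegetated voxels among all voxels in that stratum. Five strata are
standard: forest floor (FF, 0.5–1 m), shrubs (Sh, 1–2 m), lower
understory (LU, 2–5 m), upper understory (UU, 5–10 m), and subcanopy
(Sc, 10–15.5 m). LU and UU are the modelling responses. A detailed
vertical profile uses 0.5 m slices, i.e. pairs of voxel layers.

Numerical conventions, fixed once and used everywhere: intervals are
closed below and open above (`[low, high)`), so no point or voxel is
ever double-counted across voxels, strata, slices, or grid cells; the
voxel grid is anchored at the lower corner of the plot box, so a given
cloud always yields the same grid; voxel sizes must tile the box
exactly, and misaligned stratum or slice boundaries are errors rather
than silently truncated bins. Denominators count all voxels in the
stratum — no attempt is made to exclude voxels the scanner could never
have seen, so PDI is conservative in heavily occluded upper strata.

## Height normalization

Clouds are normalized with a grid ground model: the area is tiled at
`ground_resolution` (default 1 m); each cell's ground elevation is the
mean of its ground-classified points (LAS class 2) when a
classification is present, otherwise the cell minimum; empty cells are
filled from neighbours; and the cell-centre grid is interpolated
bilinearly at each point. The classified-ground mean is unbiased on
sloped terrain, whereas a minimum is biased low by about half the slope
times the cell size; the minimum is kept for unclassified clouds as the
conservative choice. This is adequate for the gentle terrain the
workflow assumes; users with demanding terrain can pre-normalize with a
dedicated tool and pass heights straight through.

## ALS metrics

ALS metrics use first returns only, capped at 22 m and thresholded at
0.5 m, so that ALS and TLS describe comparable height ranges. The
seventeen metrics are: `HMEAN`, `RHMEAN`, `SDH`, `HCV`, `HS`, `HK`
(mean, mean relative to the maximum, standard deviation, coefficient of
variation, skewness and kurtosis of first-return heights); `HM_1_3`,
`HM_2_3`, `HM_3_3` and `SD_1_3`, `SD_2_3`, `SD_3_3` (mean and standard
deviation inside each third of the height range); and `OGP`, `PTN`,
`PP_1_3`, `PP_2_3`, `PP_3_3` (non-ground fraction, point count, and the
thirds' point proportions).

Three reading choices deserve a note, since the conventional
definitions leave them open:

* *Thirds boundaries.* "One third of the maximum height" is read as the
  unit's own maximum after the 22 m cap, not a fixed 22 m, with bands
  `[floor, H/3)`, `[H/3, 2H/3)`, `[2H/3, H]` (top band closed so the
  maximum point counts once).
* *OGP versus the floor.* OGP is the fraction of non-ground first
  returns among **all** first returns, so it is computed before the
  0.5 m floor is applied; `prepare_als()` records it as an attribute.
  Non-ground means class ≠ 2 when a ground classification exists,
  otherwise height above the floor. `PTN` counts the prepared
  (post-floor) points.
* *Moment estimators.* `HS` and `HK` are the moment-based sample
  skewness and non-excess kurtosis (n denominators), the dominant
  convention in lidar metric suites.

Empty units report missing metrics; dispersion metrics require at least
two points in the relevant set.

## The understory model

`understory_model()` is the package's central estimator: ordinary least
squares of a plot-level PDI (LU or UU) on ALS metrics. Candidate
metrics pass a Pearson screen — significant correlation (two-sided,
`p < 0.05`) with `|r| > 0.7` — with no multiplicity correction. The
absolute value matters: a metric that tracks understory density
negatively is just as informative. Because lidar metric suites are
internally correlated, the screened set is truncated to the
`max_predictors` (default 2) metrics with the largest `|r|` — plot
studies of a couple dozen plots cannot support more, and published
understory models end with one or two terms. Writing the model formula
with an explicit right-hand side (e.g. `UU ~ HM_1_3`) bypasses
screening and the cap, which is how a published model is replicated on
new data.

Accuracy reporting pairs the adjusted R² of the full-data fit with the
RMSE of leave-one-out held-out predictions, normalized by the observed
response range:

nRMSE = RMSE / (y_max − y_min).

Held-out residuals were chosen for the RMSE because they measure what a
map user experiences — prediction on plots the model never saw —
whereas full-fit residuals flatter the model. LOOCV is computed exactly
through the hat-matrix identity `e(i) = e_i / (1 − h_ii)` and is
verified in the test suite against n explicit refits; a leverage of one
(a fold whose design is rank-deficient) is an error that names the
fold. Predicted PDI is clamped to [0, 1] — the linear model does not
know PDI is a fraction.

Field validation uses the conventional proxies: per-plot counts of
small trees (DBH < 9 cm) and intermediate trees (9–20 cm),
rank-correlated (Spearman) against LU and UU PDI respectively.

## Wall-to-wall prediction

`grid_metrics()` tiles the ALS coverage into 25 m cells (origin snapped
to multiples of the cell size, so the tiling is independent of the
cloud's bounding box) and computes the same seventeen metrics per cell,
each cell passing through `prepare_als()` exactly like a plot. Cells
with fewer than `min_points = 10` prepared points are dropped as
unreliable. `predict_map()` applies a fitted model and returns a
raster; outputs are written as ESRI ASCII grid (a plain-text raster
format read by all GIS stacks) plus a tidy CSV of cell predictions.

## The synthetic scene simulator

Scenes are built on the same 0.5 × 0.5 × 0.25 m lattice the TLS
pipeline analyses: the set of occupied voxels *is* the vegetation, so
per-stratum truth is exact by construction and independent of any
sampled cloud. A scene has Poisson-placed overstory stems with
lognormal DBH and ellipsoidal crowns, trunk columns, and clumped
understory foliage realized by hierarchical Bernoulli thinning (1 m
blocks active with probability √p, voxels inside active blocks with
probability √p), which gives exactly the requested expected occupancy
p while producing metre-scale clumps. Field tree lists couple small and
intermediate tree counts to the LU and UU intensities so the Spearman
validation has signal.

`sample_tls()` draws Poisson point counts per occupied voxel, thinned
with height, plus dense ground returns; at the default density every
occupied voxel receives the five points the occupancy rule demands with
overwhelming probability. `sample_als()` works top-down: each pulse is
intercepted by every crown it crosses with probability
1 − transmission (beech-like stands transmit 0.3, pine-like 0.6, which
reproduces the dense-versus-open penetration contrast), then by each
occupied sub-canopy voxel of its column with probability
`p_understory = 0.35`, else it returns from the ground. Occlusion is
probabilistic per crossing, not ray-traced: it is orders of magnitude
faster and preserves the property that matters, namely that denser
canopies let monotonically fewer pulses reach the understory.

What the simulator does *not* emulate: waveform radiometry, multiple
returns per pulse, scan-angle geometry, leaf phenology, registration
error between instruments, and the fine-scale spatial correlation of
real vegetation. Passing tests therefore demonstrate the correctness of
the algorithms and the internal consistency of the chain — not that any
particular forest will yield the same model accuracy.

### The linear-link mode

Parameter-recovery experiments need a known true relationship between
an ALS metric and understory density. `simulate_linear_link_study()`
engineers one. Each plot has a lower foliage layer spanning
[2, 2 + w] m whose thickness w (1–3 m across plots) drives the expected
mean height of sub-H/3 returns; a sparse emergent canopy near 21.5 m
pins the maximum height, hence H/3 ≈ 7.3 m; and the response layer is
confined to [7.5, 10) m — entirely above any realizable H/3 — so the
true UU PDI can be set to

true UU PDI = β · E[HM_1_3] + α + ε,  ε ~ N(0, 0.04²),

without feeding back on the predictor. `expected_hm13()` computes
E[HM_1_3] exactly from the realized geometry under the same top-down
interception model the sampler uses, so β (default 0.28) is a genuine
known truth. Because the response layer occupies the upper half of the
5–10 m stratum, truth can reach at most 0.5; the defaults span roughly
0.05–0.5. The noise level was chosen so the plot-level correlation sits
near 0.95 — strong enough for the |r| > 0.7 screen, weak enough that
the confidence-interval coverage check is not vacuous — and the default
pulse density (4 m⁻²) keeps the predictor's sampling error small
relative to the across-plot spread, so errors-in-variables attenuation
is negligible against the slope's standard error.

## Pipeline, formats, and reproducibility

The `run_*()` functions (`run_simulate`, `run_tls_pdi`,
`run_als_metrics`, `run_fit`, `run_predict_map`, `run_validate_field`,
`run_replicate`) orchestrate the stages around a flat `run_config()`
whose defaults are the protocol values quoted above; a thin command
line sits in `inst/cli/understory.R`. Every run writes a JSON manifest
(config echo, seed, versions), and identical config plus seed
reproduces byte-identical CSV outputs.

Point clouds are read and written as LAS 1.2 through a minimal reader
included in the package (record formats 0–5 on input, format 0 with a
1 mm coordinate scale on output); compressed LAZ must be decompressed
first. Tables are plain CSV; rasters are ESRI ASCII grid.

Problem sizes in the shipped tests and acceptance script are plot-scale
by design: single 27 m plots, studies of 4–24 plots, coverages of
around a hectare, and 200-replicate recovery experiments — large enough
to exercise every code path and the statistical guarantees, small
enough to run on a laptop in minutes.

## Known limitations

* PDI denominators ignore occlusion, so TLS-derived densities in upper
  strata of very dense stands are lower bounds.
* The linear model is deliberately simple; curvature in UU residuals
  (visible in the diagnostic plot) is reported, not modelled, and
  uncertainty rasters are out of scope.
* The grid-minimum/ground-mean normalization assumes gentle terrain.
* The LAS reader covers the common uncompressed profiles only.
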