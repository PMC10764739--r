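---
title: "Yield stability zones and field-relative soil health: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Yield stability zones and field-relative soil health: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yszsoil)
```

## The problem

Commercial grain fields are not homogeneous: multi-year yield-monitor
histories show that some parts of a field yield consistently high, some
consistently low, and some swing from year to year with the weather. These
*yield stability zones* (YSZ) integrate the effects of topography, soil
formation and management on the soil resource, and they are a practical
stratification layer for soil organic carbon (SOC) sampling in carbon-market
measurement, reporting and verification (MRV), where the within-field spatial
variance of SOC can dwarf the management signal one is trying to detect.

`yszsoil` implements the full analysis chain: interpolate yield-monitor
points to grids, classify multi-year stacks into four zones, derive terrain
covariates, compute Solvita/Haney-style soil health scores from laboratory
panels, and run the field-relative stratification statistics. Because real
yield-monitor and laboratory data are rarely shareable, the package also
contains a first-class synthetic-study generator with known ground truth;
every stage of the pipeline is exercised and tested against it.

## Zone classification

For a stack of per-year yield grids, each year is first centred on its own
field mean: `r = 100 (y - Ybar_t) / Ybar_t` (percent of the field-year
mean). Working in percent makes years with different absolute yields
commensurable and gives the classification thresholds their meaning. Per
cell:

* **yield level** — the temporal mean of `r`;
* **yield stability** — the temporal sample SD of `r` (denominator n − 1).

A cell is **US** (unstable) when its stability exceeds 15%, otherwise **LS**
below −10% level, **HS** above +10%, **MS** between. All comparisons are
strict, so a cell sitting exactly on a threshold falls to the stable /
medium side. Cells observed in fewer than `min_year_fraction` (default 0.8)
of years become nodata rather than being imputed. A relative-NDVI stack can
be fed through the identical code path when yield-monitor data are missing.

One wording ambiguity deserves a note: stability could also be read as a
per-year field-level SD averaged cell-by-cell. That quantity is constant
across cells within a year and cannot separate stable from unstable cells,
so the per-cell temporal SD is the implemented (and only operable) reading.

## Interpolation

Yield monitors deliver semi-regular points; the classifier needs grids.
`fit_variogram()` bins the empirical semivariogram (lags up to half the
maximum pair distance) and fits a spherical model by weighted least squares
with pair-count weights; `krige_to_grid()` solves the ordinary-kriging
system per cell using the nearest 64 points (an explicit approximation to
global kriging). With a zero nugget the predictor is exact at data
locations. Duplicate coordinates are averaged first, with a warning. Cells
more than 10 m outside the convex hull of the points are nodata —
extrapolation is not attempted. `idw_to_grid()` is the fallback when
variogram fitting is impossible; its predictions are convex and therefore
range-bounded. All grids travel through a minimal matrix-backed container
with ESRI ASCII (plain text) I/O, readable by any GIS.

## Terrain

Slope and aspect use Horn's 3×3 kernel, with one-cell linear extrapolation
at the edges so planar surfaces are exact to the boundary. Aspect is the
downslope-facing azimuth, degrees clockwise from north, undefined on flats.
Flow routing uses single-direction D8 on a depression-filled surface: the
iterative Planchon–Darboux-style fill imposes an epsilon gradient (default
1 µm) so every interior cell keeps a strictly descending path to the
boundary, which makes the router total and deterministic; equal-drop ties
go to the lowest neighbour index in row-major order. Accumulation is in
cell counts including the cell itself, so it is ≥ 1 and its log10 — the
covariate used in the statistics, as accumulation is approximately
lognormal — is always defined. Off-grid outflow sums to the cell count
(mass conservation), which the tests verify against a graph-reachability
oracle.

## Soil health scores

The Solvita-Nexus soil health score combines six indicators — CO2-burst,
Solvita colour, SLAN, water-stable aggregates, water-soluble organic C and
SOC — as

> SHS = 10 × Σ min(x_k / d_k, cap),

with maximum-value scaling factors d = (250, 5.25, 400, 80, 400, 3.5) in
the indicators' units. The per-term cap (default 1) is a design choice: the
scaling factors are described as maxima, and without a cap a single
saturated indicator could dominate; with it each indicator contributes at
most 10 points, so six terms span 0–60. The cap is configurable because the
source scoring scheme's stated 0–50 range cannot be reconciled with six
equally weighted terms times ten; we document the discrepancy rather than
silently reweight.

The nutrient index NI is the equal-weight mean of capped measured /
recommended ratios for Mehlich-1 P, Mehlich-1 K and available N
(water-soluble NO3-N plus mineralisable N estimated linearly from the
CO2-burst; the 0.1 mg N per mg CO2-C default coefficient is a placeholder
magnitude to be calibrated per laboratory). Crop recommendations are user
inputs. The overall fertility score is exactly `OFS = NI/2 + SHS`.

## Statistics

The analysis battery mirrors standard practice in field-scale soil
research:

* **Field-relative z-scores** `(x − field mean)/field SD` remove the
  regional signal so within-field stratification pools across fields.
  Per-depth analyses z-score within field × depth; the combined 0–30 cm
  analysis averages the two depth increments per core and z-scores within
  field.
* **Correlation matrices** are pairwise-complete Pearson with t-based
  two-sided p-values and 0.05/0.01/0.001 stars.
* **Stepwise regression** starts from the full OLS model and steps
  bidirectionally by AIC (`stats::step`); exactly collinear candidates
  (e.g. the third texture fraction) are detected via aliasing and dropped
  with a warning. Under pure noise, plain AIC retains a junk predictor with
  probability P(χ²₁ > 2) ≈ 0.157, so the intercept-only model is selected
  in about 60% of null replicates with three candidates — a property the
  tests assert in closed form.
* **Zone ANOVA** is classical one-way, reported with η² = SS_between /
  SS_total, Tukey HSD 95% family-wise intervals, and a median-centred
  (Brown–Forsythe) Levene test.
* **Bootstrapped post-hoc power** resamples within zones preserving group
  sizes and counts ANOVA detections at level α. The naive version of this
  estimator is badly miscalibrated at the null (≈ 0.30 for four groups of
  15, not α): every resample inherits the observed between-group sampling
  noise. By default the package therefore shrinks the group means so the
  resampling population carries the unbiased between-group sum of squares
  SS_b − (k−1) MS_w — the bootstrap analogue of estimating the
  noncentrality by (k−1)(F−1). This brings the null mean to ≈ 0.13 (median
  0.07). A residual upward bias remains because the effect estimate is
  truncated at zero and power is convex near the null; no effect-preserving
  resampling scheme can reach exactly α, which we flag rather than hide.
* **Management contrasts** average the per-field HS − LS difference of a
  z-scored response within levels of a management flag, by depth, with no
  inferential test attached: ten fields support trend description, not
  hypothesis tests.

## The synthetic-study generator

The generator is the package's test bed, and its defaults *are* the study
conditions: ten Midwest-like fields spanning a precipitation, temperature
and texture gradient, with an equal tillage/no-till split, eight
cover-cropped fields and six prescription-N fields; 3 cores × 4 zones ×
10 fields = 120 cores, split into 0–15 and 15–30 cm for 240 samples.

**Terrain** is a planar tilt plus random Gaussian mounds and depressions.
**Zones** are latent patches tied to that terrain: unstable patches sit on
high-flow-accumulation, gentle positions (swales), low-stable patches on
the steepest remaining cells, high-stable on the gentlest, with 20 m patch
smoothing; target area shares are 10/59/13/18% for LS/MS/HS/US. **Yields**
follow `y(i,t) = Ybar_t (1 + L(i)/100 + U(i) w_t + ε)`: a ±15% planted
level in LS/HS patches, a shared year shock with SD 25% switched on in
unstable cells (recentred and rescaled exactly, so the planted instability
is not at the mercy of a twelve-draw sample SD), and 5% cell-year noise.

**Soil metrics** are drawn per core and depth as
`field_mean(depth) + offset_z × depth_factor × field_SD + noise`. The zone
offsets (−0.52, −0.14, +0.37, +0.29 field-SD units for LS/MS/HS/US) are
chosen so the pairwise zone-mean gaps equal the reported field pattern
(HS−LS 0.89, US−LS 0.81, US−MS 0.43, HS−MS 0.51 SD at 0–30 cm). The depth
factors 2/(1+a) and 2a/(1+a) with amplification a = 1.4 deepen the effect
while keeping the 0–30 cm mean on target, consistent with the roughly
doubled effect size observed at depth. Within-zone noise is 0.8 field-SD
units per row, half of its variance shared between the two depths of a
core; 0.8 puts the combined-depth zone η² near 0.21 and gives the default
study ≈ 95% bootstrapped power — and it is the calibration under which the
pipeline separates LS from HS and US by Tukey HSD in ≥ 90% of replicate
studies. Note one consequence: because the empirical within-field SD under
this noise level is about 0.78 of the configured field-SD unit, the
realized z-scored zone differences run some 10–20% above the configured
offsets; the configured gaps, the separation requirement and the z-score
denominator cannot all be matched simultaneously at 30 samples per zone,
and we prioritised the separation property.

**Regional structure**: field-mean SOC rises with clay and falls with mean
annual temperature (coefficients +0.12 %/% and −0.39 %/°C), plus a 3.4%
intercept chosen so absolute SOC spans a realistic 0.7–3.1% across the
default fields, and 0.1% field-level noise calibrated so the pairwise
clay–SOC R² lands near 0.7 and stepwise selection recovers clay and MAT
with correct signs in ≥ 90% of replicates. The remaining five score
components co-vary with SOC through per-metric offset scalings and a
shared-noise loading of 0.6, which reproduces the strong collinearity seen
among soil-health indicators. No-till fields widen the HS−LS gap by
+0.4 SD at the surface and narrow it by 0.4 SD at depth, the pattern the
management contrasts are tested to recover.

What the generator does *not* emulate: harvester artifacts (overlaps,
headland passes), spatially autocorrelated soil noise within zones,
weather time series beyond the year shocks, and mechanistic crop growth.
Passing tests therefore demonstrate that the statistical machinery recovers
planted structure under realistic effect sizes and noise — not that any
particular real field behaves like the generator.

## Numerical choices and degenerate inputs

* Seeds: a single master seed; per-field seeds derive from a string hash of
  the field id, so reordering the field list changes nothing. All sampling
  goes through scoped RNG (`withr`) and never disturbs the caller's state.
* Problem sizes: examples and tests run fields of 120–240 m at 2–4 m
  resolution; replicate batteries use 30×30-cell fields, where a full
  ten-field study generates in under a second. All sizes are configuration,
  not code.
* Zero-variance fields: the variogram fitter returns a flagged zero-sill
  model and kriging degrades to the constant; z-scoring a constant field
  yields missing values with a warning; the ANOVA refuses groups of fewer
  than two observations by name.
* Boundary ties in classification fall to the stable/medium side (strict
  inequalities); D8 ties break to the lowest row-major neighbour index;
  texture triples are closed to sum exactly 100.

## Known limitations

* Kriging is isotropic ordinary kriging with a spherical model only — no
  universal kriging, anisotropy, or harvester-track cleaning.
* The ANOVA pools z-scored samples across fields rather than modelling
  field as a factor or random effect; this follows the z-scoring logic of
  the analysis it implements, but a mixed model would be the modern choice.
* The bootstrap power estimator retains a small positive null bias by
  construction (see above).
* Zone-wise terrain summaries (mean slope, log accumulation by zone) match
  the qualitative ordering of field observations — LS steepest, US
  water-gathering — but their magnitudes depend on the synthetic terrain
  and grid size and are not calibrated quantities.
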