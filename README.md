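# yszsoil

Yield stability zones (YSZ) and field-relative soil health analysis for
precision agriculture and soil-carbon MRV.

## What it does

Multi-year yield-monitor histories reveal that parts of a field yield
consistently high (HS), consistently low (LS), in between (MS), or swing
with the weather (unstable, US). These zones integrate topography, soil
formation and management, and they stratify within-field soil organic
carbon (SOC) far more effectively than blind sampling — which matters
because within-field SOC heterogeneity is typically several times larger
than the management signal a carbon-market protocol is trying to verify.

`yszsoil` provides the whole analysis chain as composable R functions:

* **Interpolation** — spherical-variogram fitting and ordinary kriging of
  yield-monitor points to 2 m grids, with an IDW fallback
  (`fit_variogram()`, `krige_to_grid()`, `idw_to_grid()`).
* **Classification** — per-cell yield level (temporal mean of the percent
  deviation from the field-year mean) and stability (temporal SD); LS
  below −10%, HS above +10%, US above 15% SD, MS otherwise
  (`relative_yield()`, `ysz_classify()`, `zone_areas()`,
  `design_samples()`).
* **Terrain** — Horn slope/aspect, depression filling, D8 flow
  accumulation with log10 transform (`terrain_rasters()`,
  `sample_at_points()`).
* **Scores** — the Solvita-Nexus soil health score
  `SHS = 10 Σ min(x_k/d_k, 1)` over six indicators with scaling factors
  (250, 5.25, 400, 80, 400, 3.5), the nutrient index NI, and the overall
  fertility score `OFS = NI/2 + SHS` (`shs()`, `nutrient_index()`,
  `ofs()`, `score_table()`).
* **Statistics** — field-relative z-scoring, Pearson correlation matrices,
  bidirectional stepwise regression by AIC, one-way ANOVA with Tukey HSD /
  eta-squared / Levene, bias-corrected bootstrapped post-hoc power, and
  HS−LS management contrasts (`field_zscore()`, `stepwise_mlr()`,
  `anova_tukey()`, `bootstrap_power()`, `management_contrast()`).
* **Synthetic studies** — a generator with known ground truth (latent
  zones tied to terrain, calibrated zone effect sizes, a regional
  clay/temperature SOC gradient) so the full pipeline runs and is tested
  without any field data (`generate_study()`, `zone_effect_profile()`).

Grids are plain-text ESRI ASCII rasters (`read_ascii_grid()` /
`write_ascii_grid()`); points are CSV or GeoJSON; one YAML file drives the
staged pipeline (`run_pipeline()`, or `inst/scripts/ysz_pipeline.R` from a
shell).

## Worked example

```r
library(yszsoil)

study <- generate_study(default_study_fields(width = 200, height = 200,
                                             res = 4), seed = 1)
study
#> <ysz_study> 10 fields, 240 sample rows (120 cores)

zone_areas(study$fields[["SR1"]]$ysz)
#>   zone n_cells area_ha pct_of_classified
#> 1   LS     251  0.4016                10
#> 2   MS    1480  2.3680                59
#> 3   HS     319  0.5104                13
#> 4   US     450  0.7200                18

stats <- study_statistics(study$samples, n_iter = 2000, seed = 1)
stats
#> <ysz_stats> 240 samples / 120 cores
#>
#> Zone ANOVA on field-relative SOC (0-30 cm):
#> <ysz_anova> F(3, 116) = 6.773, p = 0.0003, eta^2 = 0.149
#>   Levene (median-centred): F = 3.528, p = 0.0172
#>    pair   diff      lwr     upr   p_adj
#> 1 LS-HS -0.848 -1.45266 -0.2435 0.00216
#> 2 MS-HS -0.638 -1.24293 -0.0338 0.03423
#> 3 US-HS -0.039 -0.64354  0.5656 0.99831
#> 4 MS-LS  0.210 -0.39486  0.8143 0.80260
#> 5 US-LS  0.809  0.20454  1.4137 0.00379
#> 6 US-MS  0.599 -0.00519  1.2040 0.05291
#>
#> Bootstrapped power: 94.8% (2000 iterations)
#> Regional SOC model: adj R^2 = 0.89 [clay_pct, silt_pct, mat]
```

Reading the output: the ten synthetic fields were classified from their
generated 12-year yield stacks; the SR1 field splits into the four zones
with 18% unstable area. Across all fields, the zone effect on
field-relative SOC is significant (p = 3×10⁻⁴) with the low-and-stable
zone carrying about 0.8 SD less SOC than the high-and-stable and unstable
zones (Tukey-adjusted p < 0.005 for both pairs), a medium effect size
(η² ≈ 0.15), and ~95% bootstrapped power for the sampling design of
3 cores × 4 zones × 10 fields. The regional stepwise model recovers the
planted gradient: SOC rises with clay and falls with mean annual
temperature.

The same stages can be driven from a shell:

```sh
Rscript inst/scripts/ysz_pipeline.R all --outdir ysz_out --seed 1
```

which writes per-field rasters (elevation, yields, zones, terrain), the
sample CSVs and a JSON statistics report, each stage with a provenance
sidecar.

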