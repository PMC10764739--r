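Package: yszsoil
Title: Yield Stability Zones and Field-Relative Soil Health Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Classifies agricultural fields into yield stability zones (YSZ)
    from multi-year yield rasters, interpolates yield-monitor point data by
    ordinary kriging, derives terrain covariates (slope, aspect, D8 flow
    accumulation), computes Solvita/Haney-style soil health (SHS) and overall
    fertility (OFS) scores from soil-sample panels, and runs the
    field-relative stratification statistics used in precision-agriculture
    soil carbon monitoring: per-field z-scoring, correlation matrices,
    stepwise regression by AIC, one-way ANOVA with Tukey HSD and eta-squared,
    Levene tests, bootstrapped post-hoc power, and management contrasts.
    Includes a synthetic-study generator with known ground truth so the full
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    car,
    pracma,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
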