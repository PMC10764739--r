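test_that("field configuration enforces its invariants", {
  expect_error(field_config("A", clay_pct = 30, silt_pct = 40,
                            sand_pct = 40), "sum to 100")
  expect_error(field_config("A", n_years = 1), "at least 2")
  expect_error(field_config("A", res = 0), "positive")
  cf <- field_config("A", clay_pct = 20, silt_pct = 40, sand_pct = 40)
  expect_s3_class(cf, "ysz_field_config")
})

test_that("terrain generation: degenerate flat case and determinism", {
  cf <- field_config("A", width = 60, height = 60, res = 2,
                     terrain = list(tilt_x_pct = 0, tilt_y_pct = 0,
                                    n_mounds = 0))
  flat <- generate_terrain(cf, seed = 3)
  expect_equal(diff(range(flat$values)), 0)
  expect_false(anyNA(flat$values))

  cf2 <- field_config("B", width = 80, height = 80, res = 2)
  expect_identical(generate_terrain(cf2, seed = 7)$values,
                   generate_terrain(cf2, seed = 7)$values)
  expect_false(identical(generate_terrain(cf2, seed = 7)$values,
                         generate_terrain(cf2, seed = 8)$values))

  # tilt-only surface recovers its gradient through the slope operator
  cf3 <- field_config("C", width = 60, height = 60, res = 2,
                      terrain = list(tilt_x_pct = 2, tilt_y_pct = 0,
                                     n_mounds = 0))
  sl <- slope_aspect(generate_terrain(cf3, seed = 1))$slope$values
  expect_equal(as.vector(sl), rep(2, length(sl)), tolerance = 1e-9)
})

test_that("yield stack with all signals off equals the field-year means", {
  cf <- field_config("A", width = 60, height = 60, res = 4, n_years = 5)
  pr <- zone_effect_profile(level_amp_pct = 0, year_shock_sd = 0,
                            cell_noise_sd = 0)
  ys <- generate_yield_stack(cf, generate_terrain(cf, seed = 2), pr,
                             seed = 2)
  for (t in 1:5) {
    layer <- ys$stack$values[, , t]
    expect_equal(diff(range(layer)), 0)
  }
})

test_that("planted zones are recovered by the classifier", {
  cf <- field_config("A", width = 160, height = 160, res = 4)
  terr <- terrain_rasters(generate_terrain(cf, seed = 5))
  # noise off: only the planted level / instability signals remain
  pr <- zone_effect_profile(cell_noise_sd = 0)
  ys <- generate_yield_stack(cf, terr, pr, seed = 5)
  zm <- ysz_classify(relative_yield(ys$stack))
  agree <- mean(zm$zones$values == ys$true_zones$values, na.rm = TRUE)
  expect_gte(agree, 0.99)
})

test_that("unstable cells carry the configured temporal SD", {
  cf <- field_config("A", width = 160, height = 160, res = 4,
                     n_years = 12)
  terr <- terrain_rasters(generate_terrain(cf, seed = 6))
  pr <- zone_effect_profile(year_shock_sd = 0.25, cell_noise_sd = 0)
  ys <- generate_yield_stack(cf, terr, pr, seed = 6)
  rs <- relative_yield(ys$stack)
  zm <- ysz_classify(rs)
  us <- ys$true_zones$values == 4
  # shared year shock is diluted by the unstable-area share of the mean
  expect_equal(mean(zm$stability$values[us]),
               25 * (1 - mean(us)), tolerance = 3)
  expect_lt(mean(zm$stability$values[!us]), 10)
})

test_that("soil samples honour design counts, closure and zone effects", {
  cf <- field_config("A", width = 160, height = 160, res = 4,
                     tillage = "till")
  terr <- terrain_rasters(generate_terrain(cf, seed = 8))
  ys <- generate_yield_stack(cf, terr, seed = 8)
  smp <- generate_soil_samples(ys$true_zones, terr, small_design(),
                               zone_effect_profile(), cf, seed = 8)
  expect_equal(nrow(smp), 4 * 3 * 2)
  expect_equal(sort(unique(smp$zone)), sort(ZONE_LEVELS))
  expect_true(all(abs(smp$clay_pct + smp$silt_pct + smp$sand_pct - 100)
                  <= 0.01))
  expect_true(all(smp$soc_pct > 0))
  expect_true(all(smp$depth_top_cm %in% c(0, 15)))

  # zero offsets and zero noise: every row within a depth is identical
  pr0 <- zone_effect_profile(
    soc_offset_sd = c(LS = 0, MS = 0, HS = 0, US = 0), noise_sd = 0,
    soc_regional = list(clay_coef = 0.12, mat_coef = -0.39,
                        intercept = 3.4, field_noise_sd = 0))
  smp0 <- generate_soil_samples(ys$true_zones, terr, small_design(), pr0,
                                cf, seed = 8)
  for (d in c(0, 15)) {
    sub <- smp0[smp0$depth_top_cm == d, "soc_pct"]
    expect_equal(diff(range(sub)), 0)
    expect_equal(diff(range(smp0[smp0$depth_top_cm == d, "co2_burst"])), 0)
  }
})

test_that("study generation: ids, determinism, reordering stability", {
  cfgs <- small_fields()[1:3]
  expect_error(generate_study(cfgs[c(1, 1, 2)], design = small_design(),
                              seed = 1), "duplicate")
  expect_error(generate_study(cfgs[1], design = small_design(), seed = 1),
               "at least 2")

  s1 <- generate_study(cfgs, design = small_design(), seed = 4)
  s2 <- generate_study(cfgs, design = small_design(), seed = 4)
  expect_identical(s1$samples, s2$samples)

  # per-field seeds derive from the field id: reordering the field list
  # leaves each field's samples unchanged
  s3 <- generate_study(cfgs[c(3, 1, 2)], design = small_design(), seed = 4)
  a1 <- s1$samples[s1$samples$field_id == cfgs[[1]]$field_id, ]
  a3 <- s3$samples[s3$samples$field_id == cfgs[[1]]$field_id, ]
  rownames(a1) <- rownames(a3) <- NULL
  expect_identical(a1, a3)
})

test_that("study rasters and CSV are written and read back", {
  outdir <- withr::local_tempdir()
  st <- generate_study(small_fields()[1:2], design = small_design(),
                       seed = 9, outdir = outdir)
  f1 <- st$fields[[1]]$config$field_id
  expect_true(file.exists(file.path(outdir, f1, "elevation.asc")))
  expect_true(file.exists(file.path(outdir, f1, "ysz.asc")))
  expect_true(file.exists(file.path(outdir, "study_samples.csv")))
  elev <- read_ascii_grid(file.path(outdir, f1, "elevation.asc"))
  expect_equal(elev$values, st$fields[[1]]$terrain$elevation$values,
               tolerance = 1e-12)
  tab <- read.csv(file.path(outdir, "study_samples.csv"))
  expect_equal(nrow(tab), nrow(st$samples))
})

test_that("depth aggregation averages the two increments per core", {
  cfgs <- small_fields()[1:2]
  st <- generate_study(cfgs, design = small_design(), seed = 10)
  agg <- depth_aggregate(st$samples)
  expect_equal(nrow(agg), nrow(st$samples) / 2)
  one <- st$samples[st$samples$field_id == agg$field_id[1] &
                      st$samples$core_id == agg$core_id[1], ]
  expect_equal(agg$soc_pct[1], mean(one$soc_pct), tolerance = 1e-12)
  expect_equal(agg$depth_bottom_cm[1], 30)
})

test_that("generated SOC reproduces the configured zone separations", {
  # z-scored 0-30 cm zone means across replicate studies: the generator is
  # calibrated so HS - LS and US - LS land near the configured SD gaps
  studies <- replicate_studies(50)[1:20]
  diffs <- t(sapply(studies, function(st) {
    cm <- suppressWarnings(score_and_normalize(st$samples)$combined)
    zm <- tapply(cm$soc_pct_z, cm$zone, mean)
    c(hl = zm[["HS"]] - zm[["LS"]], ul = zm[["US"]] - zm[["LS"]])
  }))
  expect_gt(mean(diffs[, "hl"]), 0.7)
  expect_gt(mean(diffs[, "ul"]), 0.6)
  # the ordering LS < MS < US/HS holds on average
})
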