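#' Configuration of one synthetic field
#'
#' Holds the per-field study conditions: extent and grid resolution, the
#' number of yield-history years, the regional covariates (mean annual
#' temperature and precipitation, field-mean soil texture) and the
#' management flags.
#'
#' @param field_id unique field name.
#' @param width,height field extent, m.
#' @param res grid resolution, m per cell (default 2).
#' @param n_years years of yield history (default 12; at least 2).
#' @param mat mean annual temperature, deg C.
#' @param map_mm mean annual precipitation, mm.
#' @param clay_pct,silt_pct,sand_pct field-mean texture, % (must sum to 100
#'   within 0.01).
#' @param tillage `"till"` or `"no-till"`.
#' @param cover_crop `"yes"` or `"no"`.
#' @param n_rate `"uniform"` or `"prescription"`.
#' @param base_yield_t_ha long-term mean yield, t/ha (default 10).
#' @param terrain list of terrain-synthesis parameters: `tilt_x_pct`,
#'   `tilt_y_pct` (planar tilt, % rise eastward / northward), `n_mounds`,
#'   `mound_height_m`, `mound_radius_m`.
#' @param seed per-field seed; when `NULL` one is derived from the study
#'   master seed and the field id.
#' @return object of class `ysz_field_config`.
#' @export
field_config <- function(field_id, width = 240, height = 240, res = 2,
                         n_years = 12, mat = 10, map_mm = 1000,
                         clay_pct = 20, silt_pct = 40, sand_pct = 40,
                         tillage = c("till", "no-till"),
                         cover_crop = c("yes", "no"),
                         n_rate = c("uniform", "prescription"),
                         base_yield_t_ha = 10,
                         terrain = list(), seed = NULL) {
  if (width <= 0 || height <= 0 || res <= 0) {
    stop("field extent and resolution must be positive", call. = FALSE)
  }
  if (n_years < 2L) stop("need at least 2 yield years", call. = FALSE)
  if (abs(clay_pct + silt_pct + sand_pct - 100) > 0.01) {
    stop("texture percentages must sum to 100 (within 0.01)", call. = FALSE)
  }
  terr <- utils::modifyList(
    list(tilt_x_pct = 1.2, tilt_y_pct = 0.6, n_mounds = 6,
         mound_height_m = 1.5, mound_radius_m = 45),
    terrain
  )
  structure(list(
    field_id = as.character(field_id), width = width, height = height,
    res = res, n_years = as.integer(n_years), mat = mat, map_mm = map_mm,
    clay_pct = clay_pct, silt_pct = silt_pct, sand_pct = sand_pct,
    tillage = match.arg(tillage), cover_crop = match.arg(cover_crop),
    n_rate = match.arg(n_rate), base_yield_t_ha = base_yield_t_ha,
    terrain = terr, seed = seed
  ), class = "ysz_field_config")
}

#' Zone effect profile: the ground truth the generator plants
#'
#' All soil-metric offsets are expressed in within-field SD units so they
#' transfer across fields with different absolute levels. The default SOC
#' offsets are chosen so the zone-mean differences reproduce the reported
#' field pattern (HS - LS = 0.89, US - LS = 0.81, US - MS = 0.43,
#' HS - MS = 0.51 SD at 0-30 cm); the default depth amplification of 1.4
#' makes the 15-30 cm effect about 1.4x the 0-15 cm effect, consistent with
#' the roughly doubled eta-squared at depth. The default within-zone noise
#' (0.8 SD units per depth row) is calibrated so the combined-depth
#' zone-effect eta-squared lands near 0.21.
#'
#' @param soc_offset_sd named vector LS/MS/HS/US: SOC offset of each zone in
#'   field-SD units (0-30 cm scale).
#' @param component_scale named vector: per-metric multiplier applied to the
#'   SOC offsets for the other five SHS components.
#' @param bd_scale multiplier for bulk density (negative: low zones denser).
#' @param depth_amplification ratio of the 15-30 cm to the 0-15 cm offset
#'   (>= 1 deepens the effect; the two depth factors average to 1 so the
#'   0-30 cm mean keeps the configured offset).
#' @param noise_sd within-zone noise SD per depth row, field-SD units.
#' @param core_noise_frac fraction of noise variance shared between the two
#'   depth rows of one core.
#' @param zone_frac named target area fractions of the four zones (defaults
#'   follow the reported area shares: US 18%, LS 10%, MS 59%, HS 13%).
#' @param slope_mean_pct,log_flowacc_mean reported per-zone terrain means,
#'   used to orient zone placement (LS on the steepest stable cells, US on
#'   the highest flow accumulation).
#' @param level_amp_pct latent yield-level amplitude planted in LS/HS cells
#'   (% of field mean; default 15, comfortably beyond the 10% threshold).
#' @param year_shock_sd SD of the shared year shock on unstable cells
#'   (default 0.25, i.e. 25% — beyond the 15% stability threshold).
#' @param cell_noise_sd per-cell-per-year multiplicative yield noise SD.
#' @param patch_len_m smoothing length of the latent zone patches, m.
#' @param soc_regional list `clay_coef`, `mat_coef`, `intercept`,
#'   `field_noise_sd`: field-mean SOC (%) = clay_coef * clay% +
#'   mat_coef * MAT + intercept + noise. Coefficient signs follow the
#'   regional regression (+ on clay, - on MAT); intercept and noise are
#'   calibrated so absolute SOC is realistic and the regional model R^2
#'   lands near 0.7.
#' @param soc_field_sd within-field SOC SD, % (the "field SD unit").
#' @param depth_means_scale multipliers of the field mean for the 0-15 and
#'   15-30 cm increments (surface-enriched SOC and biology).
#' @param no_till_gap_delta extra HS - LS gap (field-SD units) added in
#'   no-till fields at the two depths (default +0.4 at 0-15 cm, -0.4 at
#'   15-30 cm: no-till concentrates the contrast at the surface).
#' @return object of class `ysz_profile`.
#' @export
zone_effect_profile <- function(
    soc_offset_sd = c(LS = -0.52, MS = -0.14, HS = 0.37, US = 0.29),
    component_scale = c(co2_burst = 0.7, sol_color = 0.5, slan = 0.9,
                        wsa = 0.5, wsoc = 0.7),
    bd_scale = -0.6,
    depth_amplification = 1.4,
    noise_sd = 0.8,
    core_noise_frac = 0.5,
    zone_frac = c(LS = 0.10, MS = 0.59, HS = 0.13, US = 0.18),
    slope_mean_pct = c(LS = 2.3, MS = 1.7, HS = 1.3, US = 0.9),
    log_flowacc_mean = c(LS = 0.56, MS = 0.61, HS = 0.59, US = 1.15),
    level_amp_pct = 15,
    year_shock_sd = 0.25,
    cell_noise_sd = 0.05,
    patch_len_m = 20,
    soc_regional = list(clay_coef = 0.12, mat_coef = -0.39,
                        intercept = 3.4, field_noise_sd = 0.1),
    soc_field_sd = 0.35,
    depth_means_scale = c(1.25, 0.75),
    no_till_gap_delta = c(0.4, -0.4)) {
  stopifnot(all(is.finite(soc_offset_sd)), depth_amplification >= 1,
            noise_sd >= 0, core_noise_frac >= 0, core_noise_frac <= 1,
            abs(sum(zone_frac) - 1) < 1e-8)
  structure(list(
    soc_offset_sd = soc_offset_sd[ZONE_LEVELS],
    component_scale = component_scale, bd_scale = bd_scale,
    depth_amplification = depth_amplification,
    noise_sd = noise_sd, core_noise_frac = core_noise_frac,
    zone_frac = zone_frac[ZONE_LEVELS],
    slope_mean_pct = slope_mean_pct[ZONE_LEVELS],
    log_flowacc_mean = log_flowacc_mean[ZONE_LEVELS],
    level_amp_pct = level_amp_pct, year_shock_sd = year_shock_sd,
    cell_noise_sd = cell_noise_sd, patch_len_m = patch_len_m,
    soc_regional = soc_regional, soc_field_sd = soc_field_sd,
    depth_means_scale = depth_means_scale,
    no_till_gap_delta = no_till_gap_delta
  ), class = "ysz_profile")
}

# depth factors scaling the configured (0-30 cm) offsets per increment;
# they average to 1 so the depth-mean recovers the configured offset
depth_factors <- function(profile) {
  a <- profile$depth_amplification
  c(2 / (1 + a), 2 * a / (1 + a))
}

#' Generate a synthetic elevation surface
#'
#' Smooth surface: planar tilt plus a sum of randomly placed Gaussian mounds
#' and depressions. Reproducible for a fixed seed; no missing cells.
#'
#' @param config a [field_config()] (terrain parameters live in
#'   `config$terrain`).
#' @param seed RNG seed (default: the config's seed, else 1).
#' @return elevation [ysz_grid()] in metres.
#' @export
generate_terrain <- function(config, seed = config$seed %||% 1L) {
  stopifnot(inherits(config, "ysz_field_config"))
  tp <- config$terrain
  g <- grid_template(0, 0, config$width, config$height, config$res)
  cc <- grid_cell_centers(g)
  z <- 100 + cc$x * tp$tilt_x_pct / 100 + cc$y * tp$tilt_y_pct / 100
  if (tp$n_mounds > 0) {
    z <- z + withr::with_seed(seed, {
      mx <- stats::runif(tp$n_mounds, 0, config$width)
      my <- stats::runif(tp$n_mounds, 0, config$height)
      amp <- stats::runif(tp$n_mounds, 0.4, 1) * tp$mound_height_m *
        sample(c(-1, 1), tp$n_mounds, replace = TRUE)
      rad <- stats::runif(tp$n_mounds, 0.6, 1.4) * tp$mound_radius_m
      acc <- numeric(nrow(cc))
      for (k in seq_len(tp$n_mounds)) {
        acc <- acc + amp[k] *
          exp(-((cc$x - mx[k])^2 + (cc$y - my[k])^2) / (2 * rad[k]^2))
      }
      acc
    })
  }
  m <- matrix(NA_real_, grid_nrow(g), grid_ncol(g))
  m[cbind(cc$row, cc$col)] <- z
  ysz_grid(m, 0, 0, config$res)
}

# latent true zones tied to terrain: US on high flow accumulation, LS on the
# steepest remaining cells, HS on the gentlest; patches smoothed over
# patch_len_m
latent_zones <- function(terrain, profile, seed) {
  slope <- terrain$slope$values
  lacc <- terrain$log_flowacc$values
  k <- max(1L, round(profile$patch_len_m / (2 * terrain$slope$res)))
  withr::with_seed(seed, {
    n <- length(slope)
    wob1 <- smooth_matrix(matrix(stats::rnorm(n), nrow(slope)), k)
    wob2 <- smooth_matrix(matrix(stats::rnorm(n), nrow(slope)), k)
    s_sm <- smooth_matrix(slope, k)
    zs <- function(m) (m - mean(m)) / stats::sd(m)
    # unstable zones: water-gathering but gentle positions (swales and
    # depressions rather than steep channels)
    u_score <- rank_unit(zs(smooth_matrix(lacc, k)) - 0.4 * zs(s_sm) +
                           0.3 * zs(wob1))
    s_score <- s_sm + 0.3 * stats::sd(s_sm) / stats::sd(wob2) * wob2
    zones <- matrix(ZONE_CODES[["MS"]], nrow(slope), ncol(slope))
    us <- u_score > 1 - profile$zone_frac[["US"]]
    zones[us] <- ZONE_CODES[["US"]]
    st_rank <- rank_unit(ifelse(us, NA_real_, s_score))
    zones[!us & st_rank > 1 - profile$zone_frac[["LS"]] /
            (1 - profile$zone_frac[["US"]])] <- ZONE_CODES[["LS"]]
    zones[!us & st_rank < profile$zone_frac[["HS"]] /
            (1 - profile$zone_frac[["US"]])] <- ZONE_CODES[["HS"]]
    zones
  })
}

#' Generate a multi-year yield stack with known zone structure
#'
#' Builds latent true zones from the terrain (unstable on high flow
#' accumulation, low-and-stable on steep cells), then synthesises per-year
#' yields as `yield(i, t) = Ybar_t * (1 + L(i)/100 + U(i) w_t + eps)`:
#' `Ybar_t` a lognormal field-year mean, `L` the planted level surface
#' (about -15% in LS patches, +15% in HS), `w_t` a shared zero-mean year
#' shock (recentred and rescaled to its configured SD exactly) switched on
#' in unstable cells, and `eps` white noise. The true-zone grid is returned
#' for recovery testing.
#'
#' @param config a [field_config()].
#' @param terrain a `ysz_terrain` (or an elevation [ysz_grid()], which is
#'   expanded with [terrain_rasters()]).
#' @param profile a [zone_effect_profile()].
#' @param seed RNG seed.
#' @return list with `stack` (absolute-yield [ysz_stack()]), `true_zones`
#'   ([ysz_grid()] of codes), `level` (planted level surface, %) and
#'   `terrain`.
#' @export
generate_yield_stack <- function(config, terrain, profile =
                                   zone_effect_profile(),
                                 seed = config$seed %||% 1L) {
  stopifnot(inherits(config, "ysz_field_config"),
            inherits(profile, "ysz_profile"))
  if (inherits(terrain, "ysz_grid")) terrain <- terrain_rasters(terrain)
  ny <- config$n_years
  zones <- latent_zones(terrain, profile, derive_seed(seed, "zones"))
  nr <- nrow(zones); nc <- ncol(zones)
  res <- withr::with_seed(derive_seed(seed, "yields"), {
    level <- matrix(0, nr, nc)
    amp <- profile$level_amp_pct
    # within-zone level jitters scale with the amplitude so amp = 0 turns
    # the level signal off entirely
    level[zones == ZONE_CODES[["LS"]]] <-
      -amp + stats::rnorm(sum(zones == ZONE_CODES[["LS"]]), 0, 0.1 * amp)
    level[zones == ZONE_CODES[["HS"]]] <-
      amp + stats::rnorm(sum(zones == ZONE_CODES[["HS"]]), 0, 0.1 * amp)
    level[zones == ZONE_CODES[["MS"]]] <-
      stats::runif(sum(zones == ZONE_CODES[["MS"]]), -0.45 * amp,
                   0.45 * amp)
    level[zones == ZONE_CODES[["US"]]] <-
      stats::rnorm(sum(zones == ZONE_CODES[["US"]]), 0, 0.2 * amp)
    ybar <- config$base_yield_t_ha * exp(stats::rnorm(ny, 0, 0.12))
    w <- stats::rnorm(ny)
    w <- (w - mean(w)) / stats::sd(w) * profile$year_shock_sd
    u <- zones == ZONE_CODES[["US"]]
    arr <- array(NA_real_, c(nr, nc, ny))
    for (t in seq_len(ny)) {
      eps <- matrix(stats::rnorm(nr * nc, 0, profile$cell_noise_sd), nr, nc)
      arr[, , t] <- ybar[t] * (1 + level / 100 + u * w[t] + eps)
    }
    list(arr = arr, level = level)
  })
  g0 <- terrain$elevation
  list(
    stack = ysz_stack(res$arr, years = seq_len(ny),
                      xmin = g0$xmin, ymin = g0$ymin, res = g0$res),
    true_zones = ysz_grid(zones, g0$xmin, g0$ymin, g0$res),
    level = ysz_grid(res$level, g0$xmin, g0$ymin, g0$res),
    terrain = terrain
  )
}

# metric synthesis parameters: field-level mean as a function of the field's
# 0-30 cm SOC level, within-field SD, and depth scaling of the mean
metric_spec <- function(reg, profile) {
  ds <- profile$depth_means_scale
  list(
    co2_burst = list(mean = 45 * reg, sd = 18, depth = ds),
    sol_color = list(mean = 1.0 + 0.5 * reg, sd = 0.35, depth = ds),
    slan = list(mean = 60 * reg, sd = 25, depth = ds),
    wsa = list(mean = 25 + 8 * reg, sd = 6, depth = c(1.05, 0.95)),
    wsoc = list(mean = 55 * reg, sd = 22, depth = ds)
  )
}

#' Generate stratified soil samples for one field
#'
#' Draws `cores_per_zone` core locations per zone (honouring spacing and
#' edge buffer), samples terrain covariates at them, and synthesises the
#' soil panel per depth increment: each metric is
#' `field_mean(depth) + zone_offset_SD * depth_factor * field_SD +
#' noise_SD * field_SD * noise`, with part of the noise shared between the
#' two depths of a core and across the metrics of a row (so components are
#' realistically collinear). Field-mean SOC follows the regional gradient
#' (rising with clay, falling with MAT). In no-till fields the HS - LS gap
#' is widened at the surface and narrowed at depth by
#' `profile$no_till_gap_delta`.
#'
#' @param zones a `ysz_map`, or a zone-code [ysz_grid()] (e.g. the
#'   generator's true zones).
#' @param terrain a `ysz_terrain` for the same field.
#' @param design a [sample_design()].
#' @param profile a [zone_effect_profile()].
#' @param config the field's [field_config()].
#' @param seed RNG seed.
#' @return data.frame, one row per core x depth increment, with the
#'   documented study-table columns.
#' @export
generate_soil_samples <- function(zones, terrain, design = sample_design(),
                                  profile = zone_effect_profile(),
                                  config, seed = config$seed %||% 1L) {
  stopifnot(inherits(profile, "ysz_profile"),
            inherits(config, "ysz_field_config"))
  pts <- design_samples(zones, design, seed = derive_seed(seed, "cores"))
  pts <- sample_at_points(terrain, pts)
  nd <- length(design$depth_splits)
  fd <- depth_factors(profile)[seq_len(nd)]
  sr <- profile$soc_regional
  ns <- profile$noise_sd
  cf <- profile$core_noise_frac
  withr::with_seed(derive_seed(seed, "soil"), {
    reg <- sr$clay_coef * config$clay_pct + sr$mat_coef * config$mat +
      sr$intercept + stats::rnorm(1, 0, sr$field_noise_sd)
    reg <- max(reg, 0.3)
    ms <- metric_spec(reg, profile)
    rows <- list()
    for (ci in seq_len(nrow(pts))) {
      z <- pts$zone[ci]
      o <- profile$soc_offset_sd[[z]]
      core_draw <- stats::rnorm(1)          # shared between depths
      for (di in seq_len(nd)) {
        ds <- design$depth_splits[[di]]
        gap_adj <- 0
        if (config$tillage == "no-till" && z %in% c("HS", "LS")) {
          gap_adj <- profile$no_till_gap_delta[di] / 2 *
            (if (z == "HS") 1 else -1)
        }
        row_draw <- stats::rnorm(1)
        shared <- sqrt(cf) * core_draw + sqrt(1 - cf) * row_draw
        lam <- 0.6                          # metric loading on shared noise
        soc <- reg * profile$depth_means_scale[di] +
          (o * fd[di] + gap_adj) * profile$soc_field_sd +
          ns * profile$soc_field_sd * shared
        soc <- max(soc, 0.05)
        vals <- list(soc_pct = soc)
        for (mname in names(ms)) {
          sp <- ms[[mname]]
          off <- profile$component_scale[[mname]] * (o * fd[di] + gap_adj)
          noise <- lam * shared + sqrt(1 - lam^2) * stats::rnorm(1)
          v <- sp$mean * sp$depth[di] + off * sp$sd + ns * sp$sd * noise
          vals[[mname]] <- max(v, 0)
        }
        bd <- 1.35 * c(0.97, 1.03)[min(di, 2)] +
          profile$bd_scale * o * fd[di] * 0.08 +
          ns * 0.08 * (lam * shared + sqrt(1 - lam^2) * stats::rnorm(1))
        clay <- config$clay_pct + ns * 2 * stats::rnorm(1)
        silt <- config$silt_pct + ns * 2 * stats::rnorm(1)
        clay <- min(max(clay, 0.5), 95)
        silt <- min(max(silt, 0.5), 99 - clay)
        rows[[length(rows) + 1L]] <- data.frame(
          field_id = config$field_id, zone = z, core_id = pts$core_id[ci],
          x = pts$x[ci], y = pts$y[ci],
          depth_top_cm = ds[1], depth_bottom_cm = ds[2],
          soc_pct = vals$soc_pct, co2_burst = vals$co2_burst,
          sol_color = vals$sol_color, slan = vals$slan, wsa = vals$wsa,
          wsoc = vals$wsoc, bulk_density = max(bd, 0.8),
          clay_pct = clay, silt_pct = silt, sand_pct = 100 - clay - silt,
          mehlich_p = max(35 + 0.3 * o * 8 + ns * 8 * stats::rnorm(1), 0),
          mehlich_k = max(120 + 0.3 * o * 25 + ns * 25 * stats::rnorm(1), 0),
          ws_no3_n = max(12 + 0.3 * o * 4 + ns * 4 * stats::rnorm(1), 0),
          elevation_m = pts$elevation_m[ci], slope_pct = pts$slope_pct[ci],
          aspect_deg = pts$aspect_deg[ci],
          log_flowacc = pts$log_flowacc[ci],
          mat = config$mat, map_mm = config$map_mm,
          tillage = config$tillage, cover_crop = config$cover_crop,
          n_rate = config$n_rate
        )
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' The default ten-field study configuration
#'
#' Ten Midwest-like fields spanning a precipitation, temperature and texture
#' gradient (Michigan sands through Illinois silty clay loams), with an
#' equal split of tillage and no-till, eight cover-cropped fields and six
#' prescription-N fields. Texture triples are closed to sum exactly 100.
#'
#' @param width,height,res,n_years grid settings shared by all fields.
#' @return list of [field_config()]s.
#' @export
default_study_fields <- function(width = 240, height = 240, res = 2,
                                 n_years = 12) {
  tab <- data.frame(
    field_id = c("SR1", "ZC1", "1-Cort", "2-Well", "F-79-2", "F-71",
                 "Watt-East", "Micic-Stateline", "Horn-South", "South-Lane"),
    map_mm = c(929, 955, 938, 949, 1024, 1045, 1042, 1017, 1000, 1000),
    mat = c(9.1, 9.1, 9.3, 9.3, 9.9, 10.1, 10.1, 10.2, 12.1, 12.1),
    clay = c(20.8, 21.6, 15.0, 12.6, 9.3, 10.6, 30.4, 27.4, 29.0, 29.3),
    silt = c(36.9, 35.3, 29.6, 25.6, 23.4, 26.9, 57.8, 57.1, 67.2, 68.2),
    sand = c(42.3, 43.1, 55.4, 61.8, 67.3, 62.5, 11.8, 15.5, 3.8, 2.5),
    tillage = c("till", "till", "till", "no-till", "no-till", "no-till",
                "no-till", "no-till", "till", "till"),
    cover = c("yes", "yes", "no", "yes", "yes", "yes", "yes", "yes",
              "yes", "no"),
    n_rate = c("prescription", "prescription", "prescription",
               "prescription", "uniform", "uniform", "prescription",
               "prescription", "uniform", "uniform")
  )
  lapply(seq_len(nrow(tab)), function(i) {
    field_config(
      field_id = tab$field_id[i], width = width, height = height, res = res,
      n_years = n_years, mat = tab$mat[i], map_mm = tab$map_mm[i],
      clay_pct = tab$clay[i], silt_pct = tab$silt[i],
      sand_pct = tab$sand[i], tillage = tab$tillage[i],
      cover_crop = tab$cover[i], n_rate = tab$n_rate[i]
    )
  })
}

#' Generate a complete multi-field synthetic study
#'
#' For each field: terrain, the multi-year yield stack with latent zones,
#' yield-stability classification of the generated stack, and stratified
#' soil samples drawn from the classified map. Per-field seeds are derived
#' deterministically from the master seed and the field id, so reordering
#' the field list does not change any field's data. Optionally writes
#' per-field rasters (ESRI ASCII) and the study CSV to `outdir`.
#'
#' @param configs list of [field_config()]s (at least 2 fields; unique ids).
#' @param profile shared [zone_effect_profile()].
#' @param design shared [sample_design()].
#' @param thresholds [ysz_thresholds()] for the classification stage.
#' @param seed master seed.
#' @param outdir optional output directory.
#' @return object of class `ysz_study`: `samples` (the long study table),
#'   `fields` (per-field list with `terrain`, `stack`, `true_zones`,
#'   `ysz`), `profile`, `design`, `seed`.
#' @export
generate_study <- function(configs = default_study_fields(),
                           profile = zone_effect_profile(),
                           design = sample_design(),
                           thresholds = ysz_thresholds(),
                           seed = 1L, outdir = NULL) {
  ids <- vapply(configs, function(cf) cf$field_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate field_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(configs) < 2L) {
    stop("a study needs at least 2 fields for regional statistics",
         call. = FALSE)
  }
  fields <- list()
  samples <- list()
  for (cf in configs) {
    fseed <- cf$seed %||% derive_seed(seed, cf$field_id)
    elev <- generate_terrain(cf, seed = derive_seed(fseed, "terrain"))
    terr <- terrain_rasters(elev)
    ys <- generate_yield_stack(cf, terr, profile, seed = fseed)
    ysz <- ysz_classify(relative_yield(ys$stack), thresholds)
    smp <- generate_soil_samples(ysz, terr, design, profile, cf,
                                 seed = fseed)
    fields[[cf$field_id]] <- list(config = cf, terrain = terr,
                                  stack = ys$stack,
                                  true_zones = ys$true_zones, ysz = ysz)
    samples[[cf$field_id]] <- smp
    if (!is.null(outdir)) {
      fdir <- file.path(outdir, cf$field_id)
      dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
      write_ascii_grid(elev, file.path(fdir, "elevation.asc"))
      write_ascii_grid(ys$true_zones, file.path(fdir, "true_zones.asc"))
      write_ascii_grid(ysz$zones, file.path(fdir, "ysz.asc"))
      for (t in seq_along(ys$stack$years)) {
        write_ascii_grid(stack_layer(ys$stack, t),
                         file.path(fdir, sprintf("yield_year%02d.asc", t)),
                         digits = 8)
      }
    }
  }
  tab <- do.call(rbind, samples)
  rownames(tab) <- NULL
  if (!is.null(outdir)) {
    utils::write.csv(tab, file.path(outdir, "study_samples.csv"),
                     row.names = FALSE)
  }
  structure(list(samples = tab, fields = fields, profile = profile,
                 design = design, seed = seed),
            class = "ysz_study")
}

#' @export
print.ysz_study <- function(x, ...) {
  cat(sprintf("<ysz_study> %d fields, %d sample rows (%d cores)\n",
              length(x$fields), nrow(x$samples),
              length(unique(paste(x$samples$field_id,
                                  x$samples$core_id)))))
  invisible(x)
}

#' Aggregate depth increments to a 0-30 cm row per core
#'
#' The combined-depth analysis uses the mean of the two depth increments of
#' each core for every numeric soil variable; location, zone and field
#' covariates are carried through unchanged.
#'
#' @param table long study table with one row per core x depth.
#' @return table with one row per core, `depth_top_cm = 0`,
#'   `depth_bottom_cm = max`.
#' @export
depth_aggregate <- function(table) {
  need <- c("field_id", "core_id", "depth_top_cm", "depth_bottom_cm")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(table$field_id, table$core_id, drop = TRUE)
  num_cols <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                      c("depth_top_cm", "depth_bottom_cm"))
  first <- table[!duplicated(key), , drop = FALSE]
  # tapply returns results in factor-level order; align the kept rows
  first <- first[order(as.integer(key[!duplicated(key)])), , drop = FALSE]
  for (cl in num_cols) {
    first[[cl]] <- as.vector(tapply(table[[cl]], key, mean))
  }
  first$depth_top_cm <- 0
  first$depth_bottom_cm <- max(table$depth_bottom_cm)
  rownames(first) <- NULL
  first
}
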