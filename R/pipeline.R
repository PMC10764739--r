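#' Default pipeline configuration
#'
#' One nested list drives every stage; [read_pipeline_config()] loads the
#' same structure from YAML and validates it. Scalars here mirror the
#' constructor defaults of the corresponding modules.
#'
#' @param outdir output root directory.
#' @param seed master seed for all stochastic stages.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(outdir = "ysz_out", seed = 1L) {
  list(
    outdir = outdir,
    seed = seed,
    thresholds = list(level_pct = 10, stability_sd_pct = 15,
                      min_year_fraction = 0.8),
    design = list(cores_per_zone = 3, min_spacing_m = 20,
                  edge_buffer_m = 6),
    scaling = list(co2_burst = 250, sol_color = 5.25, slan = 400,
                   wsa = 80, wsoc = 400, soc_pct = 3.5, ratio_cap = 1),
    recommendations = list(rec_p = 50, rec_k = 150, rec_n = 25),
    stats = list(alpha = 0.05, n_iter = 10000),
    fields = list(width = 240, height = 240, res = 2, n_years = 12)
  )
}

#' Read and validate a pipeline configuration from YAML
#'
#' @param path YAML file with the [default_pipeline_config()] structure;
#'   given scalars override the defaults.
#' @return validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_pipeline_config(), user)
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L, "seed: one integer")
  chk(cfg$thresholds$level_pct > 0, "thresholds.level_pct: > 0")
  chk(cfg$thresholds$stability_sd_pct > 0,
      "thresholds.stability_sd_pct: > 0")
  chk(cfg$design$cores_per_zone >= 1, "design.cores_per_zone: >= 1")
  chk(all(unlist(cfg$scaling) > 0), "scaling: all factors > 0")
  chk(cfg$stats$alpha > 0 && cfg$stats$alpha < 1, "stats.alpha: in (0,1)")
  if (length(problems)) {
    stop("invalid configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  cfg
}

cfg_objects <- function(cfg) {
  list(
    thresholds = do.call(ysz_thresholds, cfg$thresholds),
    design = do.call(sample_design, cfg$design),
    scaling = do.call(scaling_factors, cfg$scaling),
    rec = do.call(crop_recommendations, cfg$recommendations)
  )
}

write_provenance <- function(outdir, stage, cfg) {
  jsonlite::write_json(
    list(stage = stage,
         config_hash = rlang::hash(cfg),
         seed = cfg$seed,
         package = "yszsoil",
         version = as.character(utils::packageVersion("yszsoil")),
         r_version = R.version.string),
    file.path(outdir, paste0("provenance_", stage, ".json")),
    auto_unbox = TRUE, pretty = TRUE)
}

#' Score and normalise a raw study table
#'
#' Appends SHS/NI/OFS scores, builds the combined 0-30 cm table (depth-mean
#' per core) and adds field-relative z-scores of the response and texture
#' columns. Per-depth rows are z-scored within field and depth; the 0-30 cm
#' rows within field.
#'
#' @param samples raw study table (see [generate_soil_samples()]).
#' @param scaling a [scaling_factors()].
#' @param rec a [crop_recommendations()].
#' @return list with `by_depth` (per-increment rows, z columns added) and
#'   `combined` (0-30 cm rows, z columns added).
#' @export
score_and_normalize <- function(samples, scaling = scaling_factors(),
                                rec = crop_recommendations()) {
  zcols <- c("soc_pct", "shs", "ofs", "clay_pct", "silt_pct", "sand_pct",
             "bulk_density")
  scored <- score_table(samples, scaling, rec)
  zcols <- intersect(zcols, names(scored))
  combined <- field_zscore(depth_aggregate(scored), zcols)
  scored$field_depth <- paste(scored$field_id, scored$depth_top_cm,
                              sep = "/")
  by_depth <- field_zscore(scored, zcols, field_col = "field_depth")
  by_depth$field_depth <- NULL
  list(by_depth = by_depth, combined = combined)
}

#' Full stratification statistics for a study table
#'
#' Runs the analysis battery on a scored study: regional and local
#' correlation matrices, stepwise regressions for SOC and SHS at both
#' scales, the zone ANOVA with Tukey HSD / eta-squared / Levene on the
#' field-relative 0-30 cm responses (plus per-depth eta-squared),
#' bootstrapped post-hoc power for the SOC zone effect, and the HS - LS
#' management contrasts per depth.
#'
#' @param samples raw study table.
#' @param scaling,rec scoring parameters.
#' @param alpha significance level.
#' @param n_iter bootstrap iterations for the power analysis.
#' @param seed RNG seed for the bootstrap.
#' @return object of class `ysz_stats` (a nested list of results).
#' @export
study_statistics <- function(samples, scaling = scaling_factors(),
                             rec = crop_recommendations(),
                             alpha = 0.05, n_iter = 10000, seed = 1L) {
  sn <- score_and_normalize(samples, scaling, rec)
  comb <- sn$combined
  byd <- sn$by_depth
  regional_vars <- intersect(
    c("soc_pct", "shs", "clay_pct", "silt_pct", "sand_pct", "mat",
      "map_mm", "slope_pct", "log_flowacc"), names(comb))
  local_vars <- intersect(
    c("soc_pct_z", "shs_z", "ofs_z", "co2_burst", "sol_color", "slan",
      "wsa", "wsoc", "clay_pct_z", "sand_pct_z", "bulk_density_z",
      "slope_pct", "log_flowacc"), names(comb))
  res <- list(
    n_samples = nrow(samples),
    n_cores = nrow(comb),
    regional_cor = correlation_matrix(comb, regional_vars),
    local_cor = correlation_matrix(comb, local_vars),
    regional_mlr_soc = stepwise_mlr(
      comb, "soc_pct",
      c("clay_pct", "silt_pct", "sand_pct", "mat", "map_mm")),
    regional_mlr_shs = stepwise_mlr(
      comb, "shs", c("clay_pct", "silt_pct", "sand_pct", "mat", "map_mm")),
    local_mlr_soc = stepwise_mlr(
      comb, "soc_pct_z",
      c("clay_pct_z", "sand_pct_z", "slope_pct", "log_flowacc")),
    anova_soc = anova_tukey(comb, "soc_pct_z", "zone"),
    anova_shs = anova_tukey(comb, "shs_z", "zone"),
    anova_slope = anova_tukey(comb, "slope_pct", "zone"),
    anova_logacc = anova_tukey(comb, "log_flowacc", "zone"),
    power_soc = bootstrap_power(comb, "soc_pct_z", "zone",
                                n_iter = n_iter, alpha = alpha,
                                seed = seed),
    eta_by_depth = vapply(
      sort(unique(byd$depth_top_cm)),
      function(d) anova_tukey(byd[byd$depth_top_cm == d, ],
                              "soc_pct_z", "zone")$eta_squared,
      numeric(1)),
    contrasts = lapply(
      stats::setNames(nm = intersect(c("tillage", "cover_crop", "n_rate"),
                                     names(byd))),
      function(fl) management_contrast(byd, "soc_pct_z", fl))
  )
  names(res$eta_by_depth) <-
    paste0("depth_", sort(unique(byd$depth_top_cm)), "cm")
  structure(res, class = "ysz_stats")
}

#' @export
print.ysz_stats <- function(x, ...) {
  cat(sprintf("<ysz_stats> %d samples / %d cores\n", x$n_samples,
              x$n_cores))
  cat("\nZone ANOVA on field-relative SOC (0-30 cm):\n")
  print(x$anova_soc)
  cat(sprintf("\nBootstrapped power: %.1f%% (%d iterations)\n",
              100 * x$power_soc$power, x$power_soc$n_iter))
  cat(sprintf("Regional SOC model: adj R^2 = %.2f [%s]\n",
              x$regional_mlr_soc$adj_r2,
              paste(x$regional_mlr_soc$selected, collapse = ", ")))
  invisible(x)
}

# flatten a ysz_stats object into plain lists for the JSON report
stats_to_report <- function(st) {
  mlr_part <- function(m) list(coefficients = as.list(m$coefficients),
                               adj_r2 = m$adj_r2, p = m$p_overall,
                               selected = m$selected, n = m$n)
  an_part <- function(a) list(F = a$F, df = c(a$df_between, a$df_within),
                              p = a$p, eta_squared = a$eta_squared,
                              levene_p = a$levene_p, tukey = a$tukey)
  list(
    n_samples = st$n_samples, n_cores = st$n_cores,
    regional_mlr_soc = mlr_part(st$regional_mlr_soc),
    regional_mlr_shs = mlr_part(st$regional_mlr_shs),
    local_mlr_soc = mlr_part(st$local_mlr_soc),
    anova_soc = an_part(st$anova_soc),
    anova_shs = an_part(st$anova_shs),
    anova_slope = an_part(st$anova_slope),
    anova_logacc = an_part(st$anova_logacc),
    power_soc = st$power_soc,
    eta_by_depth = as.list(st$eta_by_depth),
    contrasts = st$contrasts
  )
}

#' Run pipeline stages
#'
#' Orchestrates the stages behind one configuration: `simulate` (synthetic
#' study: rasters + raw sample CSV), `classify` (yield rasters to zone maps
#' and area tables), `terrain` (elevation to slope/aspect/flow-accumulation
#' rasters), `score` (sample CSV to scored CSV), `stats` (scored study to a
#' JSON report), or `all`. Each stage writes a provenance sidecar (config
#' hash, seed, versions). Stages read their inputs from `outdir`, so each
#' can be rerun alone once its upstream artifacts exist; a missing upstream
#' artifact raises a condition naming the stage to run.
#'
#' @param stage one of `"simulate"`, `"classify"`, `"terrain"`, `"score"`,
#'   `"stats"`, `"all"`.
#' @param config configuration list (see [default_pipeline_config()]) or a
#'   YAML path.
#' @param outdir,seed optional overrides of the config values.
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "classify", "terrain",
                                   "score", "stats"),
                         config = default_pipeline_config(),
                         outdir = NULL, seed = NULL) {
  stage <- match.arg(stage)
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  obj <- cfg_objects(cfg)
  stages <- if (stage == "all") c("simulate", "classify", "terrain",
                                  "score", "stats") else stage
  for (s in stages) {
    switch(
      s,
      simulate = {
        configs <- default_study_fields(cfg$fields$width,
                                        cfg$fields$height,
                                        cfg$fields$res,
                                        cfg$fields$n_years)
        generate_study(configs, design = obj$design,
                       thresholds = obj$thresholds,
                       seed = cfg$seed, outdir = cfg$outdir)
      },
      classify = {
        fdirs <- list.dirs(cfg$outdir, recursive = FALSE)
        fdirs <- fdirs[vapply(fdirs, function(d)
          length(list.files(d, "^yield_year")) > 0, logical(1))]
        if (!length(fdirs)) {
          stop_missing_input("no yield rasters found", "simulate")
        }
        for (d in fdirs) {
          yrs <- sort(list.files(d, "^yield_year", full.names = TRUE))
          stk <- ysz_stack(lapply(yrs, read_ascii_grid))
          zm <- ysz_classify(relative_yield(stk), obj$thresholds)
          write_ascii_grid(zm$zones, file.path(d, "ysz.asc"))
          utils::write.csv(zone_areas(zm),
                           file.path(d, "zone_areas.csv"),
                           row.names = FALSE)
        }
      },
      terrain = {
        fdirs <- list.dirs(cfg$outdir, recursive = FALSE)
        fdirs <- fdirs[file.exists(file.path(fdirs, "elevation.asc"))]
        if (!length(fdirs)) {
          stop_missing_input("no elevation rasters found", "simulate")
        }
        for (d in fdirs) {
          terr <- terrain_rasters(
            read_ascii_grid(file.path(d, "elevation.asc")))
          write_ascii_grid(terr$slope, file.path(d, "slope.asc"))
          write_ascii_grid(terr$aspect, file.path(d, "aspect.asc"))
          write_ascii_grid(terr$flow_accumulation,
                           file.path(d, "flow_accumulation.asc"))
          write_ascii_grid(terr$log_flowacc,
                           file.path(d, "log_flowacc.asc"))
        }
      },
      score = {
        f <- file.path(cfg$outdir, "study_samples.csv")
        if (!file.exists(f)) {
          stop_missing_input("study sample table not found", "simulate")
        }
        scored <- score_table(utils::read.csv(f), obj$scaling, obj$rec)
        utils::write.csv(scored,
                         file.path(cfg$outdir, "study_scored.csv"),
                         row.names = FALSE)
      },
      stats = {
        f <- file.path(cfg$outdir, "study_samples.csv")
        if (!file.exists(f)) {
          stop_missing_input("study sample table not found", "simulate")
        }
        st <- study_statistics(utils::read.csv(f), obj$scaling, obj$rec,
                               alpha = cfg$stats$alpha,
                               n_iter = cfg$stats$n_iter,
                               seed = cfg$seed)
        jsonlite::write_json(stats_to_report(st),
                             file.path(cfg$outdir, "study_stats.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
      }
    )
    write_provenance(cfg$outdir, s, cfg)
  }
  invisible(cfg$outdir)
}
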