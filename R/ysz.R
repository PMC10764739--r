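#' Zone labels and integer codes
#'
#' The four yield stability zones in canonical order: low and stable (LS),
#' medium and stable (MS), high and stable (HS), unstable (US). Zone-code
#' grids store the matching integers 1-4 (0/`NA` = nodata).
#'
#' @format `ZONE_LEVELS` is a character vector of the four labels;
#'   `ZONE_CODES` a named integer vector mapping label to grid code.
#' @export
ZONE_LEVELS <- c("LS", "MS", "HS", "US")

#' @rdname ZONE_LEVELS
#' @export
ZONE_CODES <- c(LS = 1L, MS = 2L, HS = 3L, US = 4L)

#' Multi-year yield raster stack
#'
#' Co-registered per-year yield (or relative-NDVI) grids for one field,
#' stored as a rows x cols x years array.
#'
#' @param grids list of [ysz_grid()]s sharing placement, or a 3-d array.
#' @param years integer year labels (defaults to 1..n).
#' @param xmin,ymin,res placement when `grids` is an array.
#' @return object of class `ysz_stack`.
#' @export
ysz_stack <- function(grids, years = NULL, xmin = 0, ymin = 0, res = 2) {
  if (is.list(grids)) {
    g1 <- grids[[1]]
    same <- vapply(grids, function(g) {
      identical(dim(g$values), dim(g1$values)) && g$res == g1$res &&
        g$xmin == g1$xmin && g$ymin == g1$ymin
    }, logical(1))
    if (!all(same)) stop("stack grids must be co-registered", call. = FALSE)
    arr <- array(NA_real_, c(dim(g1$values), length(grids)))
    for (t in seq_along(grids)) arr[, , t] <- grids[[t]]$values
    xmin <- g1$xmin; ymin <- g1$ymin; res <- g1$res
  } else {
    arr <- grids
    stopifnot(length(dim(arr)) == 3L)
  }
  if (is.null(years)) years <- seq_len(dim(arr)[3])
  structure(list(values = arr, years = years,
                 xmin = xmin, ymin = ymin, res = res),
            class = "ysz_stack")
}

#' @export
print.ysz_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ysz_stack> %d rows x %d cols x %d years @ %g m\n",
              d[1], d[2], d[3], x$res))
  invisible(x)
}

stack_layer <- function(s, t) {
  ysz_grid(s$values[, , t], s$xmin, s$ymin, s$res)
}

#' Relative yield: percent deviation from the field-year mean
#'
#' Centres each year's grid on its field mean: `r = 100 (y - Ybar) / Ybar`,
#' with `Ybar` the mean over that year's non-missing cells. This makes years
#' with different absolute yields comparable and makes the percent thresholds
#' of the zone classifier meaningful.
#'
#' @param stack a [ysz_stack()] of absolute yields.
#' @return a `ysz_stack` of relative yields in percent; each year's mean over
#'   non-missing cells is 0 to within 1e-9.
#' @export
relative_yield <- function(stack) {
  stopifnot(inherits(stack, "ysz_stack"))
  ny <- dim(stack$values)[3]
  if (ny < 2L) stop("need at least 2 years of yields", call. = FALSE)
  arr <- stack$values
  for (t in seq_len(ny)) {
    layer <- arr[, , t]
    if (!any(is.finite(layer))) {
      stop("year ", stack$years[t], " has no non-missing cells",
           call. = FALSE)
    }
    ybar <- mean(layer, na.rm = TRUE)
    if (ybar == 0) {
      stop("degenerate year: field mean of year ", stack$years[t], " is 0",
           call. = FALSE)
    }
    arr[, , t] <- 100 * (layer - ybar) / ybar
  }
  out <- ysz_stack(arr, years = stack$years,
                   xmin = stack$xmin, ymin = stack$ymin, res = stack$res)
  attr(out, "relative") <- TRUE
  out
}

#' Classification thresholds for yield stability zones
#'
#' @param level_pct symmetric yield-level threshold, percent (default 10):
#'   low below -10%, high above +10% of the field mean.
#' @param stability_sd_pct temporal-SD threshold, percent (default 15):
#'   unstable above it.
#' @param min_year_fraction minimum fraction of non-missing years a cell
#'   needs to be classified (default 0.8).
#' @return object of class `ysz_thresholds`.
#' @export
ysz_thresholds <- function(level_pct = 10, stability_sd_pct = 15,
                           min_year_fraction = 0.8) {
  stopifnot(level_pct > 0, stability_sd_pct > 0,
            min_year_fraction > 0, min_year_fraction <= 1)
  structure(list(level_pct = level_pct,
                 stability_sd_pct = stability_sd_pct,
                 min_year_fraction = min_year_fraction),
            class = "ysz_thresholds")
}

#' Classify cells into yield stability zones
#'
#' Per cell, the yield level is the temporal mean of relative yield and the
#' stability is its temporal sample SD (denominator n - 1). A cell is
#' unstable (US) when stability exceeds the SD threshold; otherwise low and
#' stable (LS) below the negative level threshold, high and stable (HS)
#' above the positive one, and medium and stable (MS) between. Ties at the
#' thresholds fall to the stable / medium side (strict inequalities). Cells
#' with fewer than `min_year_fraction` of years observed become nodata.
#'
#' @param rel_stack relative-yield stack from [relative_yield()] (a
#'   relative-NDVI stack works identically).
#' @param thresholds a [ysz_thresholds()].
#' @return object of class `ysz_map`: `zones` grid (codes 1 = LS, 2 = MS,
#'   3 = HS, 4 = US, `NA` = nodata), `level` and `stability` grids, and the
#'   thresholds used.
#' @export
ysz_classify <- function(rel_stack, thresholds = ysz_thresholds()) {
  stopifnot(inherits(rel_stack, "ysz_stack"),
            inherits(thresholds, "ysz_thresholds"))
  arr <- rel_stack$values
  ny <- dim(arr)[3]
  if (ny < 2L) stop("need at least 2 years to classify", call. = FALSE)
  nvalid <- apply(!is.na(arr), c(1, 2), sum)
  level <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  stab <- apply(arr, c(1, 2), stats::sd, na.rm = TRUE)
  ok <- nvalid >= thresholds$min_year_fraction * ny & nvalid >= 2L
  level[!ok] <- NA_real_
  stab[!ok] <- NA_real_
  zones <- matrix(NA_real_, nrow(level), ncol(level))
  zones[ok & stab > thresholds$stability_sd_pct] <- ZONE_CODES[["US"]]
  stable <- ok & stab <= thresholds$stability_sd_pct
  zones[stable & level < -thresholds$level_pct] <- ZONE_CODES[["LS"]]
  zones[stable & level > thresholds$level_pct] <- ZONE_CODES[["HS"]]
  zones[stable & level >= -thresholds$level_pct &
          level <= thresholds$level_pct] <- ZONE_CODES[["MS"]]
  if (!any(is.finite(zones))) {
    stop("no classifiable cells (all nodata)", call. = FALSE)
  }
  structure(
    list(zones = ysz_grid(zones, rel_stack$xmin, rel_stack$ymin,
                          rel_stack$res),
         level = ysz_grid(level, rel_stack$xmin, rel_stack$ymin,
                          rel_stack$res),
         stability = ysz_grid(stab, rel_stack$xmin, rel_stack$ymin,
                              rel_stack$res),
         thresholds = thresholds),
    class = "ysz_map"
  )
}

#' @export
print.ysz_map <- function(x, ...) {
  cat("<ysz_map>\n")
  print(zone_areas(x))
  invisible(x)
}

#' Zone label factor from a zone-code grid
#'
#' @param zones grid of zone codes (1 = LS, 2 = MS, 3 = HS, 4 = US).
#' @return factor matrix-shaped vector with levels LS, MS, HS, US.
#' @export
zone_factor <- function(zones) {
  v <- if (inherits(zones, "ysz_grid")) zones$values else zones
  factor(ZONE_LEVELS[as.vector(v)], levels = ZONE_LEVELS)
}

#' Zone area summary
#'
#' @param ysz a `ysz_map` from [ysz_classify()] (or any zone-code
#'   [ysz_grid()]).
#' @param digits rounding of the percent column (default 0, whole percent).
#' @return data.frame with `zone`, `n_cells`, `area_ha` and
#'   `pct_of_classified`.
#' @export
zone_areas <- function(ysz, digits = 0) {
  zg <- if (inherits(ysz, "ysz_map")) ysz$zones else ysz
  counts <- table(factor(ZONE_LEVELS[as.vector(zg$values)],
                         levels = ZONE_LEVELS))
  cell_ha <- zg$res^2 / 1e4
  total <- sum(counts)
  data.frame(
    zone = ZONE_LEVELS,
    n_cells = as.vector(counts),
    area_ha = as.vector(counts) * cell_ha,
    pct_of_classified = round(100 * as.vector(counts) / total, digits)
  )
}

#' Stratified soil-sampling design
#'
#' @param cores_per_zone sampling locations per zone (default 3).
#' @param depth_splits list of `c(top_cm, bottom_cm)` increments; must be
#'   contiguous from 0 (default 0-15 and 15-30 cm).
#' @param min_spacing_m minimum distance between any two cores (default 20).
#' @param edge_buffer_m exclusion band along the field boundary (default 6).
#' @return object of class `ysz_design`.
#' @export
sample_design <- function(cores_per_zone = 3,
                          depth_splits = list(c(0, 15), c(15, 30)),
                          min_spacing_m = 20, edge_buffer_m = 6) {
  stopifnot(cores_per_zone >= 0, min_spacing_m >= 0, edge_buffer_m >= 0)
  top_prev <- 0
  for (ds in depth_splits) {
    if (length(ds) != 2L || ds[1] != top_prev || ds[2] <= ds[1]) {
      stop("depth splits must be contiguous, non-overlapping increments ",
           "starting at 0", call. = FALSE)
    }
    top_prev <- ds[2]
  }
  structure(list(cores_per_zone = cores_per_zone,
                 depth_splits = depth_splits,
                 min_spacing_m = min_spacing_m,
                 edge_buffer_m = edge_buffer_m),
            class = "ysz_design")
}

#' Draw stratified core locations within a zone map
#'
#' Samples `cores_per_zone` cell centres per zone uniformly without
#' replacement among cells outside the edge buffer, rejecting draws closer
#' than `min_spacing_m` to any already-accepted core. Deterministic for a
#' fixed seed.
#'
#' @param ysz a `ysz_map` or a zone-code [ysz_grid()].
#' @param design a [sample_design()].
#' @param seed integer RNG seed.
#' @return data.frame with `core_id`, `zone`, `x`, `y`, `row`, `col`.
#' @export
design_samples <- function(ysz, design = sample_design(), seed = 1L) {
  zg <- if (inherits(ysz, "ysz_map")) ysz$zones else ysz
  stopifnot(inherits(design, "ysz_design"))
  if (design$cores_per_zone == 0L) {
    return(data.frame(core_id = character(), zone = character(),
                      x = numeric(), y = numeric(),
                      row = integer(), col = integer()))
  }
  cc <- grid_cell_centers(zg)
  cc$zone <- ZONE_LEVELS[as.vector(zg$values)[
    (cc$col - 1L) * grid_nrow(zg) + cc$row]]
  buf <- design$edge_buffer_m
  xmax <- zg$xmin + grid_ncol(zg) * zg$res
  ymax <- grid_ymax(zg)
  cc <- cc[!is.na(cc$zone) &
             cc$x >= zg$xmin + buf & cc$x <= xmax - buf &
             cc$y >= zg$ymin + buf & cc$y <= ymax - buf, , drop = FALSE]
  for (z in ZONE_LEVELS) {
    if (sum(cc$zone == z) < design$cores_per_zone) {
      stop(sprintf(
        "zone %s has only %d eligible cell(s); %d needed (edge buffer %g m)",
        z, sum(cc$zone == z), design$cores_per_zone, buf), call. = FALSE)
    }
  }
  acc <- withr::with_seed(seed, {
    picked <- list()
    ax <- numeric(0); ay <- numeric(0)
    for (z in ZONE_LEVELS) {
      pool <- cc[cc$zone == z, , drop = FALSE]
      pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
      taken <- 0L
      for (i in seq_len(nrow(pool))) {
        if (taken == design$cores_per_zone) break
        d2 <- (ax - pool$x[i])^2 + (ay - pool$y[i])^2
        if (!length(d2) || min(d2) >= design$min_spacing_m^2) {
          picked[[length(picked) + 1L]] <- pool[i, ]
          ax <- c(ax, pool$x[i]); ay <- c(ay, pool$y[i])
          taken <- taken + 1L
        }
      }
      if (taken < design$cores_per_zone) {
        stop(sprintf(
          paste0("could not place %d cores in zone %s at %g m spacing; ",
                 "relax min_spacing_m or the edge buffer"),
          design$cores_per_zone, z, design$min_spacing_m), call. = FALSE)
      }
    }
    picked
  })
  out <- do.call(rbind, acc)
  out$core_id <- sprintf("%s-%d", out$zone,
                         stats::ave(seq_len(nrow(out)), out$zone,
                                    FUN = seq_along))
  rownames(out) <- NULL
  out[, c("core_id", "zone", "x", "y", "row", "col")]
}
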