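SHS_METRICS <- c("co2_burst", "sol_color", "slan", "wsa", "wsoc", "soc_pct")

#' Scaling factors for the soil health score
#'
#' The six SHS indicators are each scaled by a maximum-value factor `d`
#' before summing; the per-term ratio is capped (default at 1) so a single
#' saturated indicator cannot dominate the score. Defaults are the published
#' factors for CO2-burst (mg CO2-C/kg), Solvita colour (log OD), SLAN
#' (mg N/kg), water-stable aggregates (volume %), water-soluble organic C
#' (mg/kg) and SOC (%): 250, 5.25, 400, 80, 400 and 3.5.
#'
#' @param co2_burst,sol_color,slan,wsa,wsoc,soc_pct scaling divisors, all
#'   positive.
#' @param ratio_cap maximum contribution of each metric/divisor ratio
#'   (default 1; with six terms and the factor 10 the score then spans
#'   0 to 60).
#' @return object of class `ysz_scaling`.
#' @export
scaling_factors <- function(co2_burst = 250, sol_color = 5.25, slan = 400,
                            wsa = 80, wsoc = 400, soc_pct = 3.5,
                            ratio_cap = 1) {
  d <- c(co2_burst = co2_burst, sol_color = sol_color, slan = slan,
         wsa = wsa, wsoc = wsoc, soc_pct = soc_pct)
  if (any(d <= 0) || ratio_cap <= 0) {
    stop("scaling factors and ratio_cap must be positive", call. = FALSE)
  }
  structure(list(d = d, ratio_cap = ratio_cap), class = "ysz_scaling")
}

#' Solvita-Nexus soil health score (SHS)
#'
#' `SHS = 10 * sum_k min(x_k / d_k, cap)` over the six indicators. Monotone
#' non-decreasing in every metric; with the default cap of 1 the range is
#' 0 to 60.
#'
#' @param panel data.frame (or one-row list) with the six metric columns
#'   `co2_burst`, `sol_color`, `slan`, `wsa`, `wsoc`, `soc_pct`; vectorised
#'   over rows.
#' @param factors a [scaling_factors()].
#' @return numeric score per row; `NA` where any metric is missing.
#' @export
shs <- function(panel, factors = scaling_factors()) {
  stopifnot(inherits(factors, "ysz_scaling"))
  panel <- as.data.frame(panel)
  miss <- setdiff(SHS_METRICS, names(panel))
  if (length(miss)) {
    stop("panel missing metric column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(panel[SHS_METRICS])
  if (any(x < 0, na.rm = TRUE)) {
    stop("soil health metrics must be non-negative", call. = FALSE)
  }
  ratios <- sweep(x, 2L, factors$d[SHS_METRICS], "/")
  ratios <- pmin(ratios, factors$ratio_cap)
  unname(10 * rowSums(ratios))
}

#' Mineralisable nitrogen estimated from the CO2-burst
#'
#' Linear proxy `N_min = coefficient * CO2_burst`. The proportionality
#' coefficient is a configuration value (default 0.1 mg N per mg CO2-C, a
#' placeholder magnitude; calibrate to the laboratory's own relationship).
#'
#' @param co2_burst mg CO2-C per kg dry soil, non-negative.
#' @param coefficient mg N released per mg CO2-C respired.
#' @return mg N per kg.
#' @export
n_min_from_co2 <- function(co2_burst, coefficient = 0.1) {
  if (any(coefficient < 0)) {
    stop("N-min coefficient must be non-negative", call. = FALSE)
  }
  if (any(co2_burst < 0, na.rm = TRUE)) {
    stop("co2_burst must be non-negative", call. = FALSE)
  }
  coefficient * co2_burst
}

#' Crop nutrient recommendations
#'
#' Recommended Mehlich-1 phosphorus and potassium and available-N levels for
#' the crop, used as the denominators of the nutrient index. These are
#' crop- and region-specific agronomic inputs; the defaults are round
#' mid-range values for Midwest row crops.
#'
#' @param rec_p,rec_k mg/kg Mehlich-1 P and K.
#' @param rec_n mg N/kg available N (water-soluble NO3-N plus mineralisable
#'   N).
#' @return object of class `ysz_recommendations`.
#' @export
crop_recommendations <- function(rec_p = 50, rec_k = 150, rec_n = 25) {
  if (any(c(rec_p, rec_k, rec_n) <= 0)) {
    stop("crop recommendations must be positive", call. = FALSE)
  }
  structure(list(rec_p = rec_p, rec_k = rec_k, rec_n = rec_n),
            class = "ysz_recommendations")
}

#' Nutrient index (NI)
#'
#' Equal-weight mean of the capped measured/recommended ratios for Mehlich-1
#' P, Mehlich-1 K and available N (water-soluble NO3-N + N-min), expressed
#' as a percent: each nutrient at or above its recommendation contributes
#' fully, so the index spans 0 to 100.
#'
#' @param panel data.frame with columns `mehlich_p`, `mehlich_k`, `ws_no3_n`
#'   and either `n_min` or `co2_burst` (from which N-min is estimated);
#'   vectorised over rows.
#' @param rec a [crop_recommendations()].
#' @param n_min_coef coefficient for [n_min_from_co2()] when `n_min` is
#'   absent.
#' @return numeric NI percent per row.
#' @export
nutrient_index <- function(panel, rec = crop_recommendations(),
                           n_min_coef = 0.1) {
  stopifnot(inherits(rec, "ysz_recommendations"))
  panel <- as.data.frame(panel)
  need <- c("mehlich_p", "mehlich_k", "ws_no3_n")
  miss <- setdiff(need, names(panel))
  if (length(miss)) {
    stop("nutrient panel missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n_min <- if ("n_min" %in% names(panel)) panel$n_min else
    n_min_from_co2(panel$co2_burst, n_min_coef)
  avail_n <- panel$ws_no3_n + n_min
  100 * (pmin(panel$mehlich_p / rec$rec_p, 1) +
           pmin(panel$mehlich_k / rec$rec_k, 1) +
           pmin(avail_n / rec$rec_n, 1)) / 3
}

#' Overall fertility score (OFS)
#'
#' `OFS = NI / 2 + SHS`: the nutrient index contributes up to 50 points on
#' top of the soil health score.
#'
#' @param ni nutrient index, percent.
#' @param shs soil health score.
#' @return numeric score.
#' @export
ofs <- function(ni, shs) {
  if (any(!is.finite(ni) | ni < 0, na.rm = TRUE) ||
      any(!is.finite(shs) | shs < 0, na.rm = TRUE)) {
    stop("NI and SHS must be finite and non-negative", call. = FALSE)
  }
  ni / 2 + shs
}

#' Score every row of a study table
#'
#' Appends `shs`, and where the nutrient columns are present also `ni` and
#' `ofs`, to a long-format sample table. Rows with missing metrics get
#' missing scores with a warning; absent required columns are an error.
#'
#' @param samples study table with the six SHS metric columns (and
#'   optionally `mehlich_p`, `mehlich_k`, `ws_no3_n`).
#' @param factors a [scaling_factors()].
#' @param rec a [crop_recommendations()].
#' @param n_min_coef coefficient for [n_min_from_co2()].
#' @return `samples` with score columns appended; row count preserved.
#' @export
score_table <- function(samples, factors = scaling_factors(),
                        rec = crop_recommendations(), n_min_coef = 0.1) {
  samples <- as.data.frame(samples)
  samples$shs <- shs(samples, factors)
  if (anyNA(samples$shs)) {
    warning(sum(is.na(samples$shs)),
            " row(s) with missing metrics scored as NA", call. = FALSE)
  }
  if (all(c("mehlich_p", "mehlich_k", "ws_no3_n") %in% names(samples))) {
    samples$ni <- nutrient_index(samples, rec, n_min_coef)
    samples$ofs <- samples$ni / 2 + samples$shs
  }
  samples
}
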