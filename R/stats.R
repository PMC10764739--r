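#' Field-relative z-scores
#'
#' Normalises columns to each field: `z = (x - field mean) / field SD`
#' (sample SD, n - 1). This removes the between-field (regional) signal so
#' within-field stratification can be compared across fields. Fields with
#' zero SD in a column get missing z-scores with a warning.
#'
#' @param table long-format study table.
#' @param columns character vector of columns to normalise.
#' @param field_col grouping column (default `"field_id"`).
#' @param suffix appended to each new column name (default `"_z"`).
#' @return `table` with z-scored twins appended.
#' @export
field_zscore <- function(table, columns, field_col = "field_id",
                         suffix = "_z") {
  miss <- setdiff(c(columns, field_col), names(table))
  if (length(miss)) {
    stop("table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (cl in columns) {
    mu <- stats::ave(table[[cl]], table[[field_col]],
                     FUN = function(v) mean(v, na.rm = TRUE))
    sdv <- stats::ave(table[[cl]], table[[field_col]],
                      FUN = function(v) stats::sd(v, na.rm = TRUE))
    z <- (table[[cl]] - mu) / sdv
    if (any(sdv == 0, na.rm = TRUE)) {
      z[sdv == 0] <- NA_real_
      warning("zero within-field SD for `", cl,
              "` in at least one field; z-scores set to NA", call. = FALSE)
    }
    table[[paste0(cl, suffix)]] <- z
  }
  table
}

star_code <- function(p) {
  ifelse(is.na(p), "", ifelse(p <= 0.001, "***",
                              ifelse(p <= 0.01, "**",
                                     ifelse(p <= 0.05, "*", ""))))
}

#' Pairwise Pearson correlation matrix
#'
#' Pearson r on pairwise-complete observations for every variable pair, with
#' r-squared, two-sided p-values from the t transform, and significance
#' stars at 0.05 / 0.01 / 0.001.
#'
#' @param table data.frame.
#' @param variables columns to correlate (numeric).
#' @return object of class `ysz_cormat`: matrices `r`, `r2`, `p`, `stars`,
#'   `n`.
#' @export
correlation_matrix <- function(table, variables) {
  miss <- setdiff(variables, names(table))
  if (length(miss)) {
    stop("table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  k <- length(variables)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  warned <- character(0)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      x <- table[[variables[i]]]; y <- table[[variables[j]]]
      ok <- is.finite(x) & is.finite(y)
      n[i, j] <- sum(ok)
      if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
      if (sum(ok) < 3L) next
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        warned <- union(warned,
                        variables[c(i, j)][c(stats::sd(x[ok]) == 0,
                                             stats::sd(y[ok]) == 0)])
        next
      }
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  if (length(warned)) {
    warning("constant variable(s) skipped: ", paste(warned, collapse = ", "),
            call. = FALSE)
  }
  structure(list(r = r, r2 = r^2, p = p,
                 stars = matrix(star_code(p), k, k,
                                dimnames = dimnames(r)), n = n),
            class = "ysz_cormat")
}

#' @export
print.ysz_cormat <- function(x, digits = 2, ...) {
  cat("<ysz_cormat> Pearson r (stars: * <= .05, ** <= .01, *** <= .001)\n")
  m <- matrix(paste0(formatC(x$r, digits = digits, format = "f"), x$stars),
              nrow(x$r), dimnames = dimnames(x$r))
  print(m, quote = FALSE)
  invisible(x)
}

#' Bidirectional stepwise regression by AIC
#'
#' Fits the full ordinary-least-squares model of `response` on `candidates`
#' (complete cases), drops candidates that are collinear to machine
#' precision, then runs bidirectional stepwise selection minimising AIC from
#' the full model. Deterministic given the data.
#'
#' @param table data.frame.
#' @param response response column name.
#' @param candidates candidate predictor column names.
#' @return object of class `ysz_mlr`: the selected `lm` fit plus
#'   `coefficients`, `adj_r2`, `p_overall`, `selected` predictor names and
#'   the AIC `trace`.
#' @export
stepwise_mlr <- function(table, response, candidates) {
  miss <- setdiff(c(response, candidates), names(table))
  if (length(miss)) {
    stop("table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dat <- table[c(response, candidates)]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) <= length(candidates) + 2L) {
    stop("need more complete rows than candidates + 2", call. = FALSE)
  }
  full_fml <- stats::reformulate(candidates, response)
  full <- stats::lm(full_fml, data = dat)
  aliased <- names(which(is.na(stats::coef(full))))
  if (length(aliased)) {
    warning("dropping collinear candidate(s): ",
            paste(aliased, collapse = ", "), call. = FALSE)
    candidates <- setdiff(candidates, aliased)
    full <- stats::lm(stats::reformulate(candidates, response), data = dat)
  }
  sel <- stats::step(full, scope = list(lower = ~1, upper = full_fml),
                     direction = "both", trace = 0)
  sm <- summary(sel)
  fstat <- sm$fstatistic
  p_overall <- if (is.null(fstat)) NA_real_ else
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(list(
    model = sel,
    coefficients = stats::coef(sel),
    adj_r2 = sm$adj.r.squared,
    p_overall = p_overall,
    selected = attr(stats::terms(sel), "term.labels"),
    trace = sel$anova,
    n = nrow(dat)
  ), class = "ysz_mlr")
}

#' @export
print.ysz_mlr <- function(x, ...) {
  cat("<ysz_mlr> selected:",
      if (length(x$selected)) paste(x$selected, collapse = " + ") else
        "(intercept only)",
      sprintf("\n  adj R2 = %.3f, overall p = %.3g, n = %d\n",
              x$adj_r2, x$p_overall, x$n))
  invisible(x)
}

#' One-way ANOVA with Tukey HSD, eta-squared and Levene test
#'
#' Classical one-way analysis of variance of a response across groups,
#' reported with the eta-squared effect size (between-group over total sum
#' of squares), Tukey honest-significant-difference 95% family-wise
#' confidence intervals for all pairwise mean differences, and a
#' median-centred (Brown-Forsythe) Levene test of variance homogeneity.
#'
#' @param table data.frame.
#' @param response response column name.
#' @param grouping grouping column name (factor or character).
#' @return object of class `ysz_anova`: `F`, `df_between`, `df_within`, `p`,
#'   `eta_squared`, `tukey` (data.frame pair/diff/lwr/upr/p_adj),
#'   `levene_stat`, `levene_p`, `group_means`.
#' @export
anova_tukey <- function(table, response, grouping) {
  miss <- setdiff(c(response, grouping), names(table))
  if (length(miss)) {
    stop("table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  y <- table[[response]]
  g <- droplevels(factor(table[[grouping]]))
  ok <- is.finite(y) & !is.na(g)
  y <- y[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(g)
  if (any(sizes < 2L)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  fit <- stats::aov(y ~ g)
  an <- stats::anova(fit)
  ss_b <- an[["Sum Sq"]][1]; ss_w <- an[["Sum Sq"]][2]
  tk <- stats::TukeyHSD(fit, conf.level = 0.95)$g
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  lev <- car::leveneTest(y ~ g, center = stats::median)
  structure(list(
    F = an[["F value"]][1],
    df_between = an[["Df"]][1], df_within = an[["Df"]][2],
    p = an[["Pr(>F)"]][1],
    eta_squared = ss_b / (ss_b + ss_w),
    tukey = tukey,
    levene_stat = lev[["F value"]][1], levene_p = lev[["Pr(>F)"]][1],
    group_means = tapply(y, g, mean)
  ), class = "ysz_anova")
}

#' @export
print.ysz_anova <- function(x, ...) {
  cat(sprintf(
    "<ysz_anova> F(%d, %d) = %.3f, p = %.3g, eta^2 = %.3f\n",
    x$df_between, x$df_within, x$F, x$p, x$eta_squared))
  cat(sprintf("  Levene (median-centred): F = %.3f, p = %.3g\n",
              x$levene_stat, x$levene_p))
  print(x$tukey, digits = 3)
  invisible(x)
}

#' Bootstrapped post-hoc power of the one-way ANOVA
#'
#' Each iteration resamples the data with replacement within each group
#' (preserving group sizes), reruns the one-way ANOVA, and counts whether
#' the group effect is detected at level `alpha`; power is the detected
#' fraction. Iterations where every group resamples to a constant are
#' skipped and counted. Deterministic per seed.
#'
#' By default the observed group means are shrunk toward the grand mean
#' before resampling so that the resampling population carries the
#' *unbiased* between-group sum of squares, `SS_between - (k - 1) MS_within`
#' (the bootstrap analogue of estimating the noncentrality by
#' `(k - 1)(F - 1)` rather than `(k - 1) F`). Without this correction the
#' naive stratified bootstrap bakes the observed sampling noise into every
#' resample and reports power far above `alpha` even for groups drawn from
#' one distribution. A residual upward bias of a few points at the null
#' remains (the truncation of the effect estimate at zero is one-sided);
#' see the methods vignette.
#'
#' @param table data.frame.
#' @param response response column name.
#' @param grouping grouping column name.
#' @param n_iter bootstrap iterations (default 10000).
#' @param alpha significance level (default 0.05).
#' @param seed integer RNG seed.
#' @param bias_correct shrink the resampling population to the unbiased
#'   effect size (default `TRUE`); `FALSE` gives the naive stratified
#'   bootstrap.
#' @return list with `power`, exact binomial 95% `ci`, `n_iter`, `skipped`.
#' @export
bootstrap_power <- function(table, response, grouping, n_iter = 10000,
                            alpha = 0.05, seed = 1L, bias_correct = TRUE) {
  y <- table[[response]]
  g <- droplevels(factor(table[[grouping]]))
  ok <- is.finite(y) & !is.na(g)
  y <- y[ok]; g <- droplevels(g[ok])
  sizes <- table(g)
  if (any(sizes < 2L)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  k <- nlevels(g)
  if (bias_correct && k >= 2L) {
    gm <- tapply(y, g, mean)
    ssb <- sum(sizes * (gm - mean(y))^2)
    msw <- sum((y - gm[as.integer(g)])^2) / (length(y) - k)
    shrink <- sqrt(max(0, 1 - (k - 1) * msw / ssb))
    if (!is.finite(shrink)) shrink <- 1  # fully degenerate data
    y <- y - (1 - shrink) * (gm[as.integer(g)] - mean(y))
  }
  ylist <- split(y, g)
  N <- length(y)
  res <- withr::with_seed(seed, {
    S <- matrix(0, n_iter, 1)  # grand sums
    SSgr <- numeric(n_iter)    # sum of group-sum^2 / n_g
    Q <- numeric(n_iter)       # total sum of squares of values
    for (yg in ylist) {
      ng <- length(yg)
      idx <- matrix(sample.int(ng, ng * n_iter, replace = TRUE), ng, n_iter)
      v <- matrix(yg[idx], ng, n_iter)
      sg <- colSums(v)
      S <- S + sg
      SSgr <- SSgr + sg^2 / ng
      Q <- Q + colSums(v^2)
    }
    ss_total <- Q - S^2 / N
    ss_between <- SSgr - S^2 / N
    ss_within <- pmax(ss_total - ss_between, 0)
    list(ss_between = as.vector(ss_between),
         ss_within = as.vector(ss_within))
  })
  skip <- res$ss_within <= 0 & res$ss_between <= 1e-12
  Fv <- (res$ss_between / (k - 1)) / (res$ss_within / (N - k))
  pv <- stats::pf(Fv, k - 1, N - k, lower.tail = FALSE)
  pv[res$ss_within <= 0 & res$ss_between > 1e-12] <- 0
  used <- !skip
  hits <- sum(pv[used] < alpha)
  if (sum(skip) > 0.01 * n_iter) {
    warning(sum(skip), " degenerate resamples skipped (> 1% of iterations)",
            call. = FALSE)
  }
  bt <- stats::binom.test(hits, sum(used))
  list(power = hits / sum(used), ci = unname(bt$conf.int),
       n_iter = n_iter, skipped = sum(skip))
}

#' Management contrasts of the within-field HS-LS difference
#'
#' For each field and depth increment, computes the difference between the
#' mean response in the high-and-stable and the low-and-stable zone, then
#' averages those per-field differences within each level of a categorical
#' management flag. No inferential test is attached: with a handful of
#' fields per category this is a descriptive trend, not a hypothesis test.
#'
#' @param table study table with `field_id`, `zone`, a depth column and the
#'   management flag.
#' @param response response column (typically a field-relative z-score).
#' @param flag management column name (e.g. `"tillage"`, `"cover_crop"`,
#'   `"n_rate"`).
#' @param depth_col depth-increment column (default `"depth_top_cm"`).
#' @return data.frame with `flag_level`, `depth_top_cm`, `mean_hs_ls_diff`,
#'   `n_fields`.
#' @export
management_contrast <- function(table, response, flag,
                                depth_col = "depth_top_cm") {
  miss <- setdiff(c("field_id", "zone", response, flag, depth_col),
                  names(table))
  if (length(miss)) {
    stop("table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  dropped <- character(0)
  for (d in sort(unique(table[[depth_col]]))) {
    td <- table[table[[depth_col]] == d, , drop = FALSE]
    for (f in unique(td$field_id)) {
      tf <- td[td$field_id == f, , drop = FALSE]
      hs <- tf[[response]][tf$zone == "HS"]
      ls <- tf[[response]][tf$zone == "LS"]
      if (!length(hs) || !length(ls) ||
          all(is.na(hs)) || all(is.na(ls))) {
        dropped <- union(dropped, as.character(f))
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        field_id = f, depth = d, flag_level = as.character(tf[[flag]][1]),
        diff = mean(hs, na.rm = TRUE) - mean(ls, na.rm = TRUE)
      )
    }
  }
  if (length(dropped)) {
    warning("field(s) missing an HS or LS sample excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  per_field <- do.call(rbind, out)
  if (is.null(per_field)) {
    stop("no field has both HS and LS samples at any depth", call. = FALSE)
  }
  agg <- stats::aggregate(diff ~ flag_level + depth, data = per_field, mean)
  cnt <- stats::aggregate(diff ~ flag_level + depth, data = per_field,
                          length)
  res <- data.frame(flag_level = agg$flag_level, depth_top_cm = agg$depth,
                    mean_hs_ls_diff = agg$diff, n_fields = cnt$diff)
  attr(res, "per_field") <- per_field
  res
}
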