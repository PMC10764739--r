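#' Define an empty target grid
#'
#' @param xmin,ymin lower-left corner, m.
#' @param width,height extent, m (rounded up to whole cells).
#' @param res cell size, m.
#' @return a [ysz_grid()] of `NA` values covering the extent.
#' @export
grid_template <- function(xmin, ymin, width, height, res = 2) {
  nc <- ceiling(width / res)
  nr <- ceiling(height / res)
  if (nc < 1L || nr < 1L) stop("extent must be positive", call. = FALSE)
  ysz_grid(matrix(NA_real_, nr, nc), xmin, ymin, res)
}

#' Validate a yield-monitor point set
#'
#' A point set is a data.frame with columns `x`, `y` (metres), `year`
#' (integer) and `yield` (mass per area, any consistent unit).
#'
#' @param points data.frame.
#' @return the data.frame, invisibly, or an error.
#' @export
validate_yield_points <- function(points) {
  need <- c("x", "y", "year", "yield")
  miss <- setdiff(need, names(points))
  if (length(miss)) {
    stop("point set missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(points$x)) || !all(is.finite(points$y))) {
    stop("point coordinates must be finite", call. = FALSE)
  }
  if (any(points$yield < 0, na.rm = TRUE)) {
    stop("yields must be non-negative", call. = FALSE)
  }
  invisible(points)
}

#' Read yield-monitor points from CSV or GeoJSON
#'
#' CSV must carry an `x,y,year,yield` header; GeoJSON must be a
#' FeatureCollection of Point features with `year` and `yield` properties.
#'
#' @param path input file; format chosen by extension.
#' @return validated points data.frame.
#' @export
read_yield_points <- function(path) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path)
    feats <- gj$features
    pts <- do.call(rbind, lapply(feats, function(f) {
      data.frame(
        x = f$geometry$coordinates[[1]],
        y = f$geometry$coordinates[[2]],
        year = as.integer(f$properties$year),
        yield = as.numeric(f$properties$yield)
      )
    }))
  } else {
    pts <- utils::read.csv(path)
  }
  validate_yield_points(pts)
  pts
}

#' Write yield-monitor points to CSV or GeoJSON
#'
#' @param points validated points data.frame.
#' @param path output file; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_yield_points <- function(points, path) {
  validate_yield_points(points)
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    feats <- lapply(seq_len(nrow(points)), function(i) {
      list(
        type = "Feature",
        geometry = list(type = "Point",
                        coordinates = c(points$x[i], points$y[i])),
        properties = list(year = points$year[i], yield = points$yield[i])
      )
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(points, path, row.names = FALSE)
  }
  invisible(path)
}

# spherical semivariance; h may be a vector/matrix
sph_gamma <- function(h, nugget, psill, range_m) {
  g <- ifelse(h <= 0, 0,
              ifelse(h >= range_m, nugget + psill,
                     nugget + psill * (1.5 * h / range_m -
                                         0.5 * (h / range_m)^3)))
  g
}

#' Fit a spherical variogram to one year of yield points
#'
#' Bins the empirical semivariogram into `n_lags` lags up to half the maximum
#' pair distance and fits nugget, sill and range of a spherical model by
#' weighted least squares (weights = pair counts per lag).
#'
#' @param points validated yield points.
#' @param year which year to use.
#' @param n_lags number of lag bins (default 15).
#' @return object of class `ysz_variogram`: `model`, `nugget`, `sill`
#'   (total sill), `range_m`, `constant` flag, and the empirical lag table.
#' @export
fit_variogram <- function(points, year, n_lags = 15) {
  validate_yield_points(points)
  p <- points[points$year == year & is.finite(points$yield), , drop = FALSE]
  if (nrow(p) < 10L) {
    stop("need at least 10 points for year ", year, " to fit a variogram",
         call. = FALSE)
  }
  d <- as.matrix(stats::dist(cbind(p$x, p$y)))
  maxd <- max(d)
  if (stats::var(p$yield) == 0 || maxd == 0) {
    return(structure(list(model = "spherical", nugget = 0, sill = 0,
                          range_m = max(maxd / 2, 1), constant = TRUE,
                          empirical = NULL),
                     class = "ysz_variogram"))
  }
  cutoff <- maxd / 2
  iu <- upper.tri(d)
  hh <- d[iu]
  gg <- 0.5 * (outer(p$yield, p$yield, "-")^2)[iu]
  keep <- hh > 0 & hh <= cutoff
  hh <- hh[keep]; gg <- gg[keep]
  bin <- pmin(ceiling(hh / (cutoff / n_lags)), n_lags)
  emp <- data.frame(
    dist = tapply(hh, bin, mean),
    gamma = tapply(gg, bin, mean),
    n = as.vector(table(bin))
  )
  emp <- emp[is.finite(emp$gamma), , drop = FALSE]
  s2 <- stats::var(p$yield)
  obj <- function(par) {
    g <- sph_gamma(emp$dist, par[1], par[2], par[3])
    sum(emp$n * (emp$gamma - g)^2)
  }
  fit <- stats::optim(
    c(nugget = max(min(emp$gamma), 1e-8), psill = s2, range_m = cutoff / 2),
    obj, method = "L-BFGS-B",
    lower = c(0, 1e-10, cutoff / 50),
    upper = c(Inf, Inf, 4 * cutoff)
  )
  structure(list(model = "spherical",
                 nugget = unname(fit$par[1]),
                 sill = unname(fit$par[1] + fit$par[2]),
                 range_m = unname(fit$par[3]),
                 constant = FALSE, empirical = emp),
            class = "ysz_variogram")
}

#' @export
print.ysz_variogram <- function(x, ...) {
  cat(sprintf("<ysz_variogram> %s: nugget %.4g, sill %.4g, range %.1f m%s\n",
              x$model, x$nugget, x$sill, x$range_m,
              if (isTRUE(x$constant)) " [constant field]" else ""))
  invisible(x)
}

# averages duplicate coordinates; warns when any collapse happens
dedup_points <- function(p) {
  key <- paste(signif(p$x, 12), signif(p$y, 12))
  if (anyDuplicated(key)) {
    warning("duplicate point locations averaged before interpolation",
            call. = FALSE)
    agg <- stats::aggregate(p["yield"], by = list(key = key), FUN = mean)
    first <- p[!duplicated(key), c("x", "y")]
    p <- cbind(first, yield = agg$yield[match(key[!duplicated(key)],
                                              agg$key)])
  }
  p
}

# TRUE for cells inside the convex hull of the points grown by `buffer` m
hull_mask <- function(px, py, cx, cy, buffer) {
  hull <- grDevices::chull(px, py)
  hx <- px[hull]; hy <- py[hull]
  inside <- pracma::inpolygon(cx, cy, hx, hy, boundary = TRUE)
  if (buffer <= 0) return(inside)
  near <- rep(FALSE, length(cx))
  idx <- which(!inside)
  if (length(idx)) {
    nh <- length(hx)
    dmin <- rep(Inf, length(idx))
    for (s in seq_len(nh)) {
      x1 <- hx[s]; y1 <- hy[s]
      x2 <- hx[s %% nh + 1L]; y2 <- hy[s %% nh + 1L]
      vx <- x2 - x1; vy <- y2 - y1
      L2 <- vx^2 + vy^2
      t <- if (L2 == 0) rep(0, length(idx)) else
        pmin(pmax(((cx[idx] - x1) * vx + (cy[idx] - y1) * vy) / L2, 0), 1)
      dmin <- pmin(dmin, sqrt((cx[idx] - (x1 + t * vx))^2 +
                                (cy[idx] - (y1 + t * vy))^2))
    }
    near[idx] <- dmin <= buffer
  }
  inside | near
}

#' Ordinary kriging of yield points to a grid
#'
#' Solves the standard ordinary-kriging system per cell using the
#' `max_neighbors` nearest points (an approximation to global kriging).
#' With a zero-nugget model, predictions at data locations reproduce the
#' observations. Cells farther than `hull_buffer` metres outside the convex
#' hull of the points are left `NA` rather than extrapolated. Predictions
#' more than 10% beyond the observed data range are possible (kriging is not
#' convex) and are counted in the `flagged_cells` attribute.
#'
#' @param points validated yield points.
#' @param year which year to interpolate.
#' @param template target grid from [grid_template()] (placement + size).
#' @param vgm fitted [fit_variogram()] model.
#' @param max_neighbors nearest points used per cell (default 64).
#' @param hull_buffer m beyond the point hull still interpolated (default 10).
#' @return list with `estimate` and `variance` grids;
#'   `attr(estimate, "flagged_cells")` counts out-of-range excursions > 10%.
#' @export
krige_to_grid <- function(points, year, template, vgm,
                          max_neighbors = 64, hull_buffer = 10) {
  stopifnot(inherits(vgm, "ysz_variogram"), inherits(template, "ysz_grid"))
  validate_yield_points(points)
  p <- points[points$year == year & is.finite(points$yield), , drop = FALSE]
  if (nrow(p) < 3L) stop("need at least 3 points to krige", call. = FALSE)
  p <- dedup_points(p)
  cc <- grid_cell_centers(template)
  ok_mask <- hull_mask(p$x, p$y, cc$x, cc$y, hull_buffer)
  est <- rep(NA_real_, nrow(cc))
  kv <- rep(NA_real_, nrow(cc))
  if (isTRUE(vgm$constant)) {
    est[ok_mask] <- mean(p$yield)
    kv[ok_mask] <- 0
  } else {
    n_use <- min(max_neighbors, nrow(p))
    for (i in which(ok_mask)) {
      d2 <- (p$x - cc$x[i])^2 + (p$y - cc$y[i])^2
      nb <- order(d2)[seq_len(n_use)]
      sol <- ok_solve(p$x[nb], p$y[nb], sqrt(d2[nb]), vgm)
      est[i] <- sum(sol$w * p$yield[nb])
      kv[i] <- max(sol$var, 0)
    }
  }
  nr <- grid_nrow(template); nc <- grid_ncol(template)
  e_m <- matrix(NA_real_, nr, nc); v_m <- matrix(NA_real_, nr, nc)
  e_m[cbind(cc$row, cc$col)] <- est
  v_m[cbind(cc$row, cc$col)] <- kv
  rng <- range(p$yield)
  span <- diff(rng)
  flagged <- sum(e_m < rng[1] - 0.1 * span | e_m > rng[2] + 0.1 * span,
                 na.rm = TRUE)
  eg <- ysz_grid(e_m, template$xmin, template$ymin, template$res)
  attr(eg, "flagged_cells") <- flagged
  list(estimate = eg,
       variance = ysz_grid(v_m, template$xmin, template$ymin, template$res))
}

# ordinary-kriging weights for one target from neighbour coords + distances
ok_solve <- function(nx, ny, d0, vgm) {
  n <- length(nx)
  h <- as.matrix(stats::dist(cbind(nx, ny)))
  A <- rbind(cbind(sph_gamma(h, vgm$nugget, vgm$sill - vgm$nugget,
                             vgm$range_m), 1),
             c(rep(1, n), 0))
  b <- c(sph_gamma(d0, vgm$nugget, vgm$sill - vgm$nugget, vgm$range_m), 1)
  # exact-interpolation convention: gamma(0) = 0 at a coincident point
  b[seq_len(n)][d0 == 0] <- 0
  sol <- tryCatch(solve(A, b), error = function(e) {
    solve(A + diag(c(rep(1e-10, n), 0)), b)
  })
  list(w = sol[seq_len(n)], var = sum(sol * b))
}

#' Inverse-distance-weighted interpolation to a grid
#'
#' Fallback interpolator when variogram fitting is not possible. Exact at
#' data locations by convention: a cell whose centre lies within half a cell
#' of a point takes that point's value. Predictions are convex combinations,
#' so they always lie within the observed data range.
#'
#' @inheritParams krige_to_grid
#' @param power distance exponent (default 2).
#' @return estimate [ysz_grid()].
#' @export
idw_to_grid <- function(points, year, template, power = 2) {
  validate_yield_points(points)
  p <- points[points$year == year & is.finite(points$yield), , drop = FALSE]
  if (nrow(p) < 1L) stop("need at least 1 point for IDW", call. = FALSE)
  p <- dedup_points(p)
  cc <- grid_cell_centers(template)
  snap <- template$res / 2
  est <- vapply(seq_len(nrow(cc)), function(i) {
    d <- sqrt((p$x - cc$x[i])^2 + (p$y - cc$y[i])^2)
    j <- which.min(d)
    if (d[j] <= snap) return(p$yield[j])
    w <- 1 / d^power
    sum(w * p$yield) / sum(w)
  }, numeric(1))
  nr <- grid_nrow(template); nc <- grid_ncol(template)
  m <- matrix(NA_real_, nr, nc)
  m[cbind(cc$row, cc$col)] <- est
  ysz_grid(m, template$xmin, template$ymin, template$res)
}
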