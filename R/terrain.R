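#' Slope and aspect from an elevation grid (Horn 3x3 kernel)
#'
#' Gradients are estimated with Horn's weighted third-order finite
#' differences. Edge cells are handled by linearly extrapolating the grid one
#' cell outward, which reduces to one-sided differences and keeps planar
#' surfaces exact to the boundary. Slope is rise/run as a percentage; aspect
#' is the direction the surface faces (downslope), degrees clockwise from
#' north, `NA` on flat cells.
#'
#' @param elev a [ysz_grid()] of elevations in metres.
#' @return list with `slope` (%) and `aspect` (degrees) grids.
#' @export
slope_aspect <- function(elev) {
  z <- elev$values
  if (nrow(z) < 3L || ncol(z) < 3L) {
    stop("elevation grid must be at least 3 x 3", call. = FALSE)
  }
  h <- elev$res
  zp <- pad_linear(z)
  nr <- nrow(z); nc <- ncol(z)
  ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
  a <- zp[ri - 1L, ci - 1L]; b <- zp[ri - 1L, ci]; cc <- zp[ri - 1L, ci + 1L]
  d <- zp[ri, ci - 1L];                             f <- zp[ri, ci + 1L]
  g <- zp[ri + 1L, ci - 1L]; hh <- zp[ri + 1L, ci]; i <- zp[ri + 1L, ci + 1L]
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * h)   # + east
  dzdy <- ((a + 2 * b + cc) - (g + 2 * hh + i)) / (8 * h)  # + north
  slope <- 100 * sqrt(dzdx^2 + dzdy^2)
  aspect <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  aspect[dzdx == 0 & dzdy == 0] <- NA_real_
  list(
    slope  = ysz_grid(slope,  elev$xmin, elev$ymin, elev$res),
    aspect = ysz_grid(aspect, elev$xmin, elev$ymin, elev$res)
  )
}

# pad a matrix by one cell on every side via linear extrapolation
pad_linear <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  zp <- rbind(2 * z[1L, ] - z[2L, ], z, 2 * z[nr, ] - z[nr - 1L, ])
  cbind(2 * zp[, 1L] - zp[, 2L], zp, 2 * zp[, nc] - zp[, nc - 1L])
}

# 8-neighbour offsets in the order N, NE, E, SE, S, SW, W, NW
D8_DROW <- c(-1L, -1L, 0L, 1L, 1L,  1L,  0L, -1L)
D8_DCOL <- c( 0L,  1L, 1L, 1L, 0L, -1L, -1L, -1L)

#' Fill closed depressions in an elevation grid
#'
#' Iterative flood fill in the style of Planchon and Darboux: the output is
#' the lowest surface that is at least the input everywhere and drains every
#' interior cell to the grid boundary. A small epsilon gradient is imposed so
#' filled areas and flats retain a strictly descending path outward, which
#' guarantees the D8 router never stalls. Idempotent: filling a filled
#' surface changes nothing.
#'
#' @param elev a [ysz_grid()] of elevations.
#' @param eps epsilon drainage increment in metres (default 1e-6).
#' @return a [ysz_grid()] of conditioned elevations, `>=` input everywhere.
#' @export
fill_depressions <- function(elev, eps = 1e-6) {
  z <- elev$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 2L || nc < 2L) return(elev)
  w <- matrix(Inf, nr, nc)
  border <- row(z) == 1L | row(z) == nr | col(z) == 1L | col(z) == nc
  w[border] <- z[border]
  repeat {
    nbmin <- neighbor_min(w)
    cand <- pmax(z, nbmin + eps)
    wnew <- pmin(w, cand)
    wnew[border] <- z[border]
    if (identical(wnew, w)) break
    w <- wnew
  }
  ysz_grid(w, elev$xmin, elev$ymin, elev$res)
}

# elementwise minimum over the 8 neighbours (Inf beyond the boundary)
neighbor_min <- function(w) {
  nr <- nrow(w); nc <- ncol(w)
  out <- matrix(Inf, nr, nc)
  for (k in seq_along(D8_DROW)) {
    di <- D8_DROW[k]; dj <- D8_DCOL[k]
    src_r <- seq_len(nr) + di
    src_c <- seq_len(nc) + dj
    ok_r <- src_r >= 1L & src_r <= nr
    ok_c <- src_c >= 1L & src_c <= nc
    sh <- matrix(Inf, nr, nc)
    sh[ok_r, ok_c] <- w[src_r[ok_r], src_c[ok_c]]
    out <- pmin(out, sh)
  }
  out
}

#' D8 flow direction and flow accumulation
#'
#' Each cell drains to its steepest-descent neighbour among the 8, with drops
#' weighted by centre distance (diagonals by sqrt(2)). Ties go to the lowest
#' neighbour index in row-major order, deterministically. Accumulation is in
#' cell counts and includes the cell itself, so it is at least 1 everywhere
#' and its log is always defined. Cells with no lower neighbour (boundary
#' outlets) drain off-grid; the sum of their accumulations equals the total
#' cell count.
#'
#' @param elev_filled a depression-filled [ysz_grid()]
#'   (see [fill_depressions()]).
#' @return list with `direction` (grid; 1..8 = N, NE, E, SE, S, SW, W, NW,
#'   0 = off-grid), `accumulation` (cell counts) and `log_flowacc`
#'   (log10 of counts) grids.
#' @export
d8_flow_accumulation <- function(elev_filled) {
  z <- elev_filled$values
  nr <- nrow(z); nc <- ncol(z)
  n <- nr * nc
  dist <- ifelse(D8_DROW != 0L & D8_DCOL != 0L, sqrt(2), 1) * elev_filled$res
  # receiver linear index (row-major cell id) per cell; 0 = off-grid
  best_drop <- matrix(0, nr, nc)
  recv <- matrix(0L, nr, nc)
  dircode <- matrix(0L, nr, nc)
  rowm_id <- function(r, c) (r - 1L) * nc + c
  ids <- matrix(rowm_id(row(z), col(z)), nr, nc)
  for (k in seq_along(D8_DROW)) {
    di <- D8_DROW[k]; dj <- D8_DCOL[k]
    nb_r <- row(z) + di; nb_c <- col(z) + dj
    ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
    drop <- matrix(-Inf, nr, nc)
    nb_val <- matrix(NA_real_, nr, nc)
    nb_val[ok] <- z[cbind(nb_r[ok], nb_c[ok])]
    drop[ok] <- (z[ok] - nb_val[ok]) / dist[k]
    nb_id <- matrix(NA_integer_, nr, nc)
    nb_id[ok] <- rowm_id(nb_r[ok], nb_c[ok])
    # strict improvement, or equal drop to a lower row-major neighbour id
    better <- drop > best_drop + 1e-15 |
      (abs(drop - best_drop) <= 1e-15 & drop > 0 &
         !is.na(nb_id) & (recv == 0L | nb_id < recv))
    better[!ok] <- FALSE
    best_drop[better] <- drop[better]
    recv[better] <- nb_id[better]
    dircode[better] <- k
  }
  # accumulate from high to low on the conditioned surface
  ord <- order(as.vector(t(z)), decreasing = TRUE) # by row-major cell id
  acc <- rep(1, n)
  recv_v <- as.vector(t(recv))
  for (c_id in ord) {
    r <- recv_v[c_id]
    if (r > 0L) acc[r] <- acc[r] + acc[c_id]
  }
  acc_m <- matrix(acc, nr, nc, byrow = TRUE)
  list(
    direction = ysz_grid(dircode, elev_filled$xmin, elev_filled$ymin,
                         elev_filled$res),
    accumulation = ysz_grid(acc_m, elev_filled$xmin, elev_filled$ymin,
                            elev_filled$res),
    log_flowacc = ysz_grid(log10(acc_m), elev_filled$xmin, elev_filled$ymin,
                           elev_filled$res)
  )
}

#' Full terrain covariate set from an elevation grid
#'
#' Convenience wrapper: Horn slope/aspect on the raw surface, then depression
#' filling and D8 flow accumulation (cell counts, log10-transformed — the
#' distribution of accumulation is approximately lognormal, so analyses use
#' the log).
#'
#' @inheritParams slope_aspect
#' @param eps epsilon passed to [fill_depressions()].
#' @return object of class `ysz_terrain`: list of grids `elevation`, `slope`,
#'   `aspect`, `filled`, `direction`, `flow_accumulation`, `log_flowacc`.
#' @export
terrain_rasters <- function(elev, eps = 1e-6) {
  sa <- slope_aspect(elev)
  filled <- fill_depressions(elev, eps = eps)
  fa <- d8_flow_accumulation(filled)
  structure(
    list(
      elevation = elev, slope = sa$slope, aspect = sa$aspect,
      filled = filled, direction = fa$direction,
      flow_accumulation = fa$accumulation, log_flowacc = fa$log_flowacc
    ),
    class = "ysz_terrain"
  )
}

#' Sample terrain covariates at point locations
#'
#' Nearest-cell lookup of elevation, slope, aspect and (log) flow
#' accumulation at each point.
#'
#' @param terrain a `ysz_terrain` from [terrain_rasters()].
#' @param points data.frame with `x` and `y` columns (metres, same frame as
#'   the grids). Points outside the extent raise an error naming them.
#' @return `points` with columns `elevation_m`, `slope_pct`, `aspect_deg`,
#'   `flow_accumulation`, `log_flowacc` appended.
#' @export
sample_at_points <- function(terrain, points) {
  stopifnot(inherits(terrain, "ysz_terrain"),
            all(c("x", "y") %in% names(points)))
  points$elevation_m <- grid_extract(terrain$elevation, points$x, points$y)
  points$slope_pct <- grid_extract(terrain$slope, points$x, points$y)
  points$aspect_deg <- grid_extract(terrain$aspect, points$x, points$y)
  points$flow_accumulation <-
    grid_extract(terrain$flow_accumulation, points$x, points$y)
  points$log_flowacc <- grid_extract(terrain$log_flowacc, points$x, points$y)
  points
}
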