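# simulate a Gaussian random field with spherical covariance at given
# points; the extent holds many correlation ranges so the sill is
# identifiable
sim_spherical_field <- function(n, sill, range_m, extent = 800) {
  x <- runif(n, 0, extent); y <- runif(n, 0, extent)
  h <- as.matrix(dist(cbind(x, y)))
  C <- sill - yszsoil:::sph_gamma(h, 0, sill, range_m)
  L <- chol(C + diag(1e-8, n))
  data.frame(x = x, y = y, year = 1L,
             yield = 10 + as.vector(t(L) %*% rnorm(n)))
}

test_that("variogram fitting: constant fields, preconditions, recovery", {
  const <- data.frame(x = runif(20, 0, 100), y = runif(20, 0, 100),
                      year = 1L, yield = 7)
  v <- fit_variogram(const, 1)
  expect_true(v$constant)
  expect_equal(v$sill, 0)

  few <- data.frame(x = 1:5, y = 1:5, year = 1L, yield = runif(5, 5, 10))
  expect_error(fit_variogram(few, 1), "at least 10")

  set.seed(51)
  sills <- replicate(20, {
    pts <- sim_spherical_field(500, sill = 4, range_m = 100)
    fit_variogram(pts, 1)$sill
  })
  # fitted sill within +/-25% of the true value in the typical replicate
  expect_lt(abs(median(sills) - 4), 1)
  expect_gt(mean(abs(sills - 4) < 1), 0.6)
})

test_that("kriging is exact at data points and constant on constant data", {
  set.seed(61)
  # data points placed on cell centres of the 10 m target grid
  pts <- data.frame(x = c(5, 25, 45, 15, 35), y = c(5, 15, 45, 45, 5),
                    year = 1L, yield = c(4, 9, 6, 8, 5))
  vgm <- structure(list(model = "spherical", nugget = 0, sill = 4,
                        range_m = 60, constant = FALSE),
                   class = "ysz_variogram")
  # 10 m grid whose cell centres hit the data points exactly
  tpl <- grid_template(0, 0, 50, 50, res = 10)
  kr <- krige_to_grid(pts, 1, tpl, vgm, hull_buffer = 50)
  pred <- grid_extract(kr$estimate, pts$x, pts$y)
  expect_equal(pred, pts$yield, tolerance = 1e-6)
  expect_true(all(kr$variance$values >= 0, na.rm = TRUE))

  const <- transform(pts, yield = 3)
  kc <- krige_to_grid(const, 1, tpl, fit_variogram(
    rbind(const, transform(const, x = x + 1)), 1), hull_buffer = 50)
  expect_true(all(abs(kc$estimate$values - 3) < 1e-9, na.rm = TRUE))
})

test_that("kriging weights match a direct linear-algebra solution", {
  pts <- data.frame(x = c(0, 30, 60), y = c(0, 10, -5), year = 1L,
                    yield = c(2, 5, 3))
  vgm <- structure(list(model = "spherical", nugget = 0.5, sill = 3,
                        range_m = 80, constant = FALSE),
                   class = "ysz_variogram")
  target <- c(20, 4)
  d0 <- sqrt((pts$x - target[1])^2 + (pts$y - target[2])^2)
  sol <- yszsoil:::ok_solve(pts$x, pts$y, d0, vgm)
  # independent oracle: build and solve the full OK system explicitly
  gam <- function(h) {
    psill <- vgm$sill - vgm$nugget
    ifelse(h <= 0, 0, ifelse(h >= vgm$range_m, vgm$nugget + psill,
                             vgm$nugget + psill * (1.5 * h / vgm$range_m -
                                                     0.5 * (h / vgm$range_m)^3)))
  }
  h <- as.matrix(dist(cbind(pts$x, pts$y)))
  A <- rbind(cbind(gam(h), 1), c(1, 1, 1, 0))
  b <- c(gam(d0), 1)
  w_direct <- solve(A, b)[1:3]
  expect_equal(unname(sol$w), unname(w_direct), tolerance = 1e-8)
  expect_equal(sum(sol$w), 1, tolerance = 1e-10)
})

test_that("duplicate data locations are averaged with a warning", {
  pts <- data.frame(x = c(5, 5, 40), y = c(5, 5, 40), year = 1L,
                    yield = c(2, 6, 3))
  tpl <- grid_template(0, 0, 50, 50, res = 10)
  expect_warning(
    kr <- krige_to_grid(pts, 1, tpl,
                        structure(list(model = "spherical", nugget = 0,
                                       sill = 2, range_m = 50,
                                       constant = FALSE),
                                  class = "ysz_variogram"),
                        hull_buffer = 50),
    "duplicate")
  expect_equal(grid_extract(kr$estimate, 5, 5), 4, tolerance = 1e-6)
})

test_that("IDW: degenerate inputs, hand-computed midpoint, range bound", {
  tpl <- grid_template(0, 0, 20, 20, res = 2)
  one <- data.frame(x = 3, y = 3, year = 1L, yield = 6.5)
  g <- idw_to_grid(one, 1, tpl)
  expect_equal(as.vector(g$values), rep(6.5, 100), tolerance = 1e-12)

  two_eq <- data.frame(x = c(2, 18), y = c(2, 18), year = 1L, yield = 4)
  expect_equal(as.vector(idw_to_grid(two_eq, 1, tpl)$values), rep(4, 100),
               tolerance = 1e-12)

  # two points 10 m apart, values 0 and 10: midpoint cell -> 5
  two <- data.frame(x = c(0, 10), y = c(1, 1), year = 1L,
                    yield = c(0, 10))
  g <- idw_to_grid(two, 1, tpl, power = 2)
  expect_equal(grid_extract(g, 5, 1), 5, tolerance = 1e-12)

  set.seed(71)
  rnd <- data.frame(x = runif(30, 0, 20), y = runif(30, 0, 20),
                    year = 1L, yield = runif(30, 2, 9))
  g <- idw_to_grid(rnd, 1, tpl)
  expect_true(all(g$values >= 2 & g$values <= 9))
})

test_that("point sets round-trip through CSV and GeoJSON", {
  pts <- data.frame(x = c(1.5, 2.25), y = c(3, -1), year = c(2019L, 2020L),
                    yield = c(8.1, 9.4))
  csv <- withr::local_tempfile(fileext = ".csv")
  gj <- withr::local_tempfile(fileext = ".geojson")
  write_yield_points(pts, csv)
  write_yield_points(pts, gj)
  expect_equal(read_yield_points(csv), pts)
  expect_equal(read_yield_points(gj), pts)
  expect_error(validate_yield_points(data.frame(x = 1, y = 1)), "missing")
})
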