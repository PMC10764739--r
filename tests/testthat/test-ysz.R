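stack_from_layers <- function(...) {
  layers <- list(...)
  ysz_stack(array(unlist(layers), c(dim(layers[[1]]), length(layers))),
            res = 2)
}

test_that("relative yield centres each year on its field mean", {
  # constant year -> all zero; cell at 1.1x mean -> exactly +10
  m <- matrix(10, 3, 3)
  m2 <- m; m2[2, 2] <- 11
  rs <- relative_yield(stack_from_layers(m, m2))
  expect_true(all(rs$values[, , 1] == 0))
  mbar <- mean(m2)
  expect_equal(rs$values[2, 2, 2], 100 * (11 - mbar) / mbar)

  # hand arithmetic: year values (8, 10, 12), mean 10 -> (-20, 0, +20)
  y1 <- matrix(c(8, 10, 12), 1, 3)
  rs <- relative_yield(stack_from_layers(y1, y1))
  expect_equal(as.vector(rs$values[, , 1]), c(-20, 0, 20))
  # per-year mean of relative yield is 0
  expect_lt(abs(mean(rs$values[, , 1])), 1e-9)

  expect_error(relative_yield(stack_from_layers(matrix(0, 2, 2),
                                                matrix(1, 2, 2))),
               "degenerate year")
  expect_error(relative_yield(ysz_stack(array(1, c(2, 2, 1)))),
               "at least 2")
})

test_that("zone rules and strict threshold boundaries", {
  mk_cell <- function(level, stab) {
    # two-year cell with exact mean `level` and sample SD `stab`
    c(level - stab / sqrt(2), level + stab / sqrt(2))
  }
  vals <- rbind(mk_cell(-12, 8), mk_cell(0, 20), mk_cell(11, 14.9),
                mk_cell(-10, 15), mk_cell(10, 15), mk_cell(0, 15),
                mk_cell(-10.01, 14), mk_cell(10.01, 14))
  arr <- array(NA_real_, c(8, 1, 2))
  arr[, 1, ] <- vals
  zm <- ysz_classify(ysz_stack(arr, res = 2))
  got <- as.character(zone_factor(zm$zones))
  expect_equal(got, c("LS", "US", "HS", "MS", "MS", "MS", "LS", "HS"))
})

test_that("classification equals the per-cell brute-force oracle", {
  set.seed(81)
  for (trial in 1:25) {
    arr <- array(rnorm(8 * 8 * 5, sd = 15), c(8, 8, 5))
    rs <- relative_yield(ysz_stack(arr + 100, res = 2))
    zm <- ysz_classify(rs)
    expect_equal(zm$zones$values, brute_force_classify(rs$values))
  }
})

test_that("classification is scale- and year-order-invariant", {
  set.seed(91)
  arr <- array(runif(6 * 6 * 6, 5, 15), c(6, 6, 6))
  base <- ysz_classify(relative_yield(ysz_stack(arr, res = 2)))
  scaled <- ysz_classify(relative_yield(ysz_stack(arr * 3.7, res = 2)))
  expect_identical(scaled$zones$values, base$zones$values)
  expect_equal(scaled$level$values, base$level$values, tolerance = 1e-9)

  perm <- ysz_classify(relative_yield(
    ysz_stack(arr[, , c(4, 1, 6, 2, 5, 3)], res = 2)))
  expect_identical(perm$zones$values, base$zones$values)
  expect_equal(perm$stability$values, base$stability$values,
               tolerance = 1e-9)
})

test_that("relative-NDVI stacks classify through the identical path", {
  set.seed(96)
  ndvi_rel <- array(rnorm(5 * 5 * 6, 0, 12), c(5, 5, 6))  # already in %
  s <- ysz_stack(ndvi_rel, res = 30)
  zm <- ysz_classify(s)
  expect_equal(zm$zones$values, brute_force_classify(ndvi_rel))
})

test_that("zone areas: cell arithmetic and rounding", {
  # 2500 LS cells at 2 m -> exactly 1 ha
  za <- zone_areas(ysz_grid(matrix(1, 50, 50), res = 2))
  expect_equal(za$area_ha[za$zone == "LS"], 1.0)
  expect_equal(za$pct_of_classified[za$zone == "LS"], 100)
  expect_equal(za$pct_of_classified[za$zone == "US"], 0)
})

test_that("sample design: counts, spacing, determinism, degenerate cases", {
  set.seed(101)
  zones <- matrix(rep(1:4, each = 100), 20, 20)  # four vertical bands
  zg <- ysz_grid(zones, res = 4)
  des <- sample_design(cores_per_zone = 3, min_spacing_m = 8,
                       edge_buffer_m = 4)
  pts <- design_samples(zg, des, seed = 5)
  expect_equal(nrow(pts), 12L)
  expect_equal(as.vector(table(pts$zone)[c("LS", "MS", "HS", "US")]),
               rep(3L, 4))
  dmat <- as.matrix(dist(pts[, c("x", "y")]))
  expect_true(all(dmat[upper.tri(dmat)] >= 8))
  expect_identical(design_samples(zg, des, seed = 5), pts)
  expect_false(identical(design_samples(zg, des, seed = 6)$x, pts$x))

  none <- design_samples(zg, sample_design(cores_per_zone = 0), seed = 1)
  expect_equal(nrow(none), 0L)

  # a zone with too few eligible cells is named in the error
  zones2 <- zones; zones2[zones2 == 4] <- 2
  zones2[10, 10] <- 4
  expect_error(design_samples(ysz_grid(zones2, res = 4), des, seed = 1),
               "US")
  # infeasible spacing suggests relaxing it
  expect_error(
    design_samples(zg, sample_design(cores_per_zone = 3,
                                     min_spacing_m = 500,
                                     edge_buffer_m = 4), seed = 1),
    "relax")
})

test_that("depth splits must be contiguous from the surface", {
  expect_error(sample_design(depth_splits = list(c(0, 15), c(20, 30))),
               "contiguous")
  expect_error(sample_design(depth_splits = list(c(5, 15))), "contiguous")
  expect_silent(sample_design(depth_splits = list(c(0, 10), c(10, 30))))
})
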