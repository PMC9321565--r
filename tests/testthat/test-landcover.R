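lc_stack <- function(codes_by_year) {
  # codes_by_year: list of matrices
  annual_stack(seq(2001, by = 1, length.out = length(codes_by_year)),
               lapply(codes_by_year, raster_grid))
}

test_that("modal land cover counts classes and breaks ties downward", {
  m <- function(x) matrix(x, 1, 1)
  s <- lc_stack(lapply(c(10, 10, 10, 8, 8), m))
  expect_equal(grid_values(mode_landcover(s))[1, 1], 10)
  all10 <- lc_stack(lapply(rep(10, 15), m))
  expect_equal(grid_values(mode_landcover(all10))[1, 1], 10)
  # 10 vs 8 tie over two years: smallest code wins
  tie <- lc_stack(lapply(c(10, 8), m))
  expect_equal(grid_values(mode_landcover(tie))[1, 1], 8)
  expect_error(mode_landcover(lc_stack(lapply(c(1.5, 2), m))),
               "integer")
})

test_that("the mode is invariant to year order", {
  set.seed(4)
  layers <- lapply(1:7, function(j) matrix(sample(c(8, 9, 10, 12), 9,
                                                  replace = TRUE), 3, 3))
  s <- lc_stack(layers)
  m1 <- grid_values(mode_landcover(s))
  for (perm in list(7:1, sample(7))) {
    s2 <- annual_stack(stack_years(s), s$layers[perm])
    expect_equal(grid_values(mode_landcover(s2)), m1)
  }
})

test_that("grassland mask selects the grass-bearing classes", {
  g <- raster_grid(matrix(c(8, 9, 10, 12, 7, NA), 2, 3))
  mask <- grassland_mask(g)
  expect_equal(grid_values(mask)[, 1], c(1, 1))   # 8, 9
  expect_equal(grid_values(mask)[1, 2], 1)        # 10
  expect_equal(grid_values(mask)[2, 2], 0)        # cropland
  expect_equal(grid_values(mask)[1, 3], 0)        # open shrub
  expect_true(is.na(grid_values(mask)[2, 3]))
  expect_error(grassland_mask(g, numeric(0)), "empty")
})

test_that("annual interpolation is exact at anchors and linear between", {
  g <- function(x) raster_grid(matrix(x, 1, 1))
  anchors <- annual_stack(c(2000, 2010), list(g(0.2), g(0.4)))
  out <- interpolate_annual(anchors, 2000:2010)
  expect_equal(grid_values(stack_layer(out, 2005))[1, 1], 0.3)
  expect_equal(grid_values(stack_layer(out, 2000))[1, 1], 0.2)
  expect_equal(grid_values(stack_layer(out, 2010))[1, 1], 0.4)
  # three anchors: piecewise-linear segments evaluated by hand
  a3 <- annual_stack(c(2000, 2005, 2015), list(g(1), g(11), g(6)))
  o3 <- interpolate_annual(a3, c(2002, 2005, 2009, 2013, 2017))
  expect_equal(grid_values(stack_layer(o3, 2002))[1, 1], 1 + 10 * 2 / 5)
  expect_equal(grid_values(stack_layer(o3, 2005))[1, 1], 11)
  expect_equal(grid_values(stack_layer(o3, 2009))[1, 1], 11 - 5 * 4 / 10)
  expect_equal(grid_values(stack_layer(o3, 2013))[1, 1], 11 - 5 * 8 / 10)
  # beyond the last anchor: nearest-anchor extension
  expect_equal(grid_values(stack_layer(o3, 2017))[1, 1], 6)
  # a single anchor extends to every target year
  one <- interpolate_annual(annual_stack(2005, list(g(7))), 2001:2010)
  expect_true(all(stack_matrix(one) == 7))
})

test_that("interpolated values stay within per-pixel anchor bounds", {
  sc <- tiny_scenario(seed = 13)
  canopy <- sc$inputs$canopy
  anchors <- annual_stack(c(2000, 2005, 2010, 2015),
                          list(canopy, canopy * 0.5, canopy * 1.5, canopy))
  out <- interpolate_annual(anchors, 2001:2015)
  m <- stack_matrix(out)
  am <- stack_matrix(anchors)
  expect_true(all(m >= apply(am, 1, min) - 1e-12))
  expect_true(all(m <= apply(am, 1, max) + 1e-12))
})

test_that("continuous resampling is an area-weighted mean excluding nodata", {
  src <- raster_grid(matrix(c(0, 1, 1, 1), 2, 2), cellsize = 1, crs = "A")
  ref <- raster_grid(matrix(0, 1, 1), cellsize = 2, crs = "A")
  out <- resample_to_reference(src, ref, "continuous")
  expect_equal(grid_values(out)[1, 1], 0.75)
  # nodata cells are left out of the average
  src2 <- raster_grid(matrix(c(NA, 1, 1, 4), 2, 2), cellsize = 1, crs = "A")
  expect_equal(grid_values(resample_to_reference(src2, ref))[1, 1], 2)
  # identical geometry is the identity
  expect_identical(resample_to_reference(src, src), src)
  # uneven overlap: 1x1 target over a shifted 2-cell source
  src3 <- raster_grid(matrix(c(10, 30), 1, 2), cellsize = 1, crs = "A")
  ref3 <- raster_grid(matrix(0, 1, 1), xll = 0.5, cellsize = 1, crs = "A")
  expect_equal(grid_values(resample_to_reference(src3, ref3))[1, 1], 20)
})

test_that("categorical resampling picks the cell containing each centre", {
  src <- raster_grid(matrix(c(8, 10, 8, 9), 2, 2), cellsize = 1, crs = "A")
  ref <- raster_grid(matrix(0, 1, 1), cellsize = 2, crs = "A")
  # centre (1,1) lies on the shared corner; the containing-cell rule
  # resolves to the cell whose interval starts there: row 2, col 2 -> 9
  expect_equal(grid_values(resample_to_reference(src, ref,
                                                 "categorical"))[1, 1], 9)
  # off-centre target picks the nearest sub-cell unambiguously
  ref2 <- raster_grid(matrix(0, 1, 1), xll = 0, yll = 1, cellsize = 1,
                      crs = "A")
  expect_equal(grid_values(resample_to_reference(src, ref2,
                                                 "categorical"))[1, 1], 8)
})

test_that("disjoint extents and mismatched CRS are refused", {
  a <- raster_grid(matrix(1, 2, 2), crs = "A")
  far <- raster_grid(matrix(1, 2, 2), xll = 100, crs = "A")
  expect_error(resample_to_reference(a, far), "disjoint")
  b <- raster_grid(matrix(1, 2, 2), crs = "B")
  expect_error(resample_to_reference(a, b), "CRS")
})
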