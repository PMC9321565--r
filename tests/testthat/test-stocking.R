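test_that("carrying capacity follows the animal-unit budget", {
  expect_equal(grid_values(carrying_capacity(g1(500)))[1, 1],
               500 * 1000 / (455 * 0.02 * 365), tolerance = 1e-12)
  expect_equal(grid_values(carrying_capacity(g1(500)))[1, 1], 150.53,
               tolerance = 1e-4)
  expect_equal(grid_values(carrying_capacity(g1(100)))[1, 1], 30.106,
               tolerance = 1e-4)
  expect_equal(grid_values(carrying_capacity(g1(0)))[1, 1], 0)
  # doubling the intake halves the capacity exactly
  cc1 <- grid_values(carrying_capacity(g1(350),
                                       animal_unit_params(daily_intake_fraction = 0.02)))
  cc2 <- grid_values(carrying_capacity(g1(350),
                                       animal_unit_params(daily_intake_fraction = 0.04)))
  expect_equal(cc1[1, 1], 2 * cc2[1, 1])
  expect_error(animal_unit_params(daily_intake_fraction = 0), "> 0")
  expect_error(animal_unit_params(daily_intake_fraction = 0.1), "0.018")
})

test_that("animal-unit conversion is a factor-weighted headcount sum", {
  au <- animal_units(list(cattle = g1(10)))
  expect_equal(grid_values(au)[1, 1], 10)
  au2 <- animal_units(list(cattle = g1(10), sheep = g1(20)))
  expect_equal(grid_values(au2)[1, 1], 10 * 1.0 + 20 * 0.125)
  expect_equal(grid_values(au2)[1, 1], 12.5)
  zeros <- animal_units(list(cattle = g1(0), goat = g1(0), horse = g1(0)))
  expect_equal(grid_values(zeros)[1, 1], 0)
  expect_error(animal_units(list(llama = g1(5))), "unknown species")
  expect_error(animal_units(list(cattle = g1(-2))), "non-negative")
  # linear in each headcount
  a <- grid_values(animal_units(list(cattle = g1(3), horse = g1(4))))[1, 1]
  b <- grid_values(animal_units(list(cattle = g1(6), horse = g1(4))))[1, 1]
  expect_equal(b - a, 3 * 1.0)
})

test_that("relative stocking density handles zero capacity explicitly", {
  expect_equal(grid_values(rsd(g1(15), g1(30)))[1, 1], 0.5)
  expect_equal(grid_values(rsd(g1(30), g1(30)))[1, 1], 1.0)
  expect_equal(grid_values(rsd(g1(0), g1(30)))[1, 1], 0)
  expect_equal(grid_values(rsd(g1(5), g1(0)))[1, 1], Inf)
  expect_true(is.na(grid_values(rsd(g1(0), g1(0)))[1, 1]))
  # scale invariance
  r1 <- grid_values(rsd(g1(7), g1(13)))[1, 1]
  r2 <- grid_values(rsd(g1(7 * 3.7), g1(13 * 3.7)))[1, 1]
  expect_equal(r1, r2)
})

test_that("pressure classes partition RSD with closed medium boundaries", {
  cls <- function(x) grid_values(classify_rsd(g1(x)))[1, 1]
  expect_equal(cls(0.10), 1)
  expect_equal(cls(0.19999), 1)
  expect_equal(cls(0.20), 2)   # boundary -> medium
  expect_equal(cls(0.40), 2)
  expect_equal(cls(0.65), 2)   # boundary -> medium
  expect_equal(cls(0.66), 3)
  expect_equal(cls(Inf), 3)    # stock on zero forage
  expect_true(is.na(cls(NA)))
  # every defined cell receives exactly one label
  set.seed(8)
  r <- raster_grid(matrix(c(runif(30, 0, 2), NA, NA), 4, 8))
  codes <- grid_values(classify_rsd(r))
  expect_equal(sum(!is.na(codes)), 30)
  expect_true(all(codes[!is.na(codes)] %in% 1:3))
  tab <- rsd_class_table(classify_rsd(r))
  expect_equal(sum(tab$n_cells), 30)
  expect_equal(sum(tab$share), 1)
})

test_that("windowed median RSD matches the sort-and-pick-middle oracle", {
  cc_stack <- annual_stack(2008:2012,
                           lapply(c(10, 20, 30, 40, 50), g1))
  med <- median_rsd_window(g1(10), cc_stack, 2008:2012)
  expect_equal(grid_values(med)[1, 1], median(10 / c(10, 20, 30, 40, 50)))
  expect_equal(grid_values(med)[1, 1], 1 / 3, tolerance = 1e-12)
  # constant capacity: reduces to the single-year ratio
  const <- annual_stack(2008:2012, lapply(rep(25, 5), g1))
  expect_equal(grid_values(median_rsd_window(g1(10), const))[1, 1], 0.4)
  # order of years is immaterial
  perm <- annual_stack(2008:2012, lapply(c(50, 10, 40, 20, 30), g1))
  expect_equal(grid_values(median_rsd_window(g1(10), perm))[1, 1], 1 / 3)
  expect_error(median_rsd_window(g1(10), cc_stack, integer(0)), "empty")
})

test_that("minimum-CC stocking density dominates the windowed median", {
  expect_equal(grid_values(rsd_min_cc(g1(8),
                                      annual_stack(2001:2002,
                                                   list(g1(10), g1(40)))))[1, 1],
               0.8)
  const <- annual_stack(2001:2003, lapply(rep(20, 3), g1))
  expect_equal(grid_values(rsd_min_cc(g1(8), const))[1, 1],
               grid_values(rsd(g1(8), g1(20)))[1, 1])
  sc <- tiny_scenario(seed = 29)
  cc <- carrying_capacity_stack(compute_agb_stack(
    sc$inputs$npp, sc$inputs$mat, sc$inputs$canopy, sc$inputs$slope))
  au <- animal_units(sc$inputs$heads)
  lo <- grid_values(median_rsd_window(au, cc))
  hi <- grid_values(rsd_min_cc(au, cc))
  ok <- !is.na(lo) & !is.na(hi)
  expect_true(any(ok))
  expect_true(all(hi[ok] >= lo[ok] - 1e-12))
})

test_that("overstocked-year share counts years above the boundary", {
  cc_stack <- annual_stack(2001:2003, lapply(c(10, 10, 100), g1))
  frac <- overstocked_year_fraction(g1(7), cc_stack)
  expect_equal(grid_values(frac)[1, 1], 2 / 3)
  expect_equal(grid_values(overstocked_year_fraction(g1(0), cc_stack))[1, 1],
               0)
  always <- overstocked_year_fraction(g1(100), cc_stack)
  expect_equal(grid_values(always)[1, 1], 1)
})

test_that("livestock-grazing masking keeps values inside, drops outside", {
  sc <- tiny_scenario(seed = 31)
  au <- animal_units(sc$inputs$heads)
  mask <- sc$inputs$grazing_mask
  kept <- mask_livestock_grazing(au, mask)
  expect_equal(sum(!is.na(grid_values(kept))),
               sum(grid_values(mask) == 1))
  inside <- grid_values(mask) == 1
  expect_equal(grid_values(kept)[inside], grid_values(au)[inside])
  all_true <- grid_set_values(mask, 1)
  expect_equal(grid_values(mask_livestock_grazing(au, all_true)),
               grid_values(au))
  all_false <- grid_set_values(mask, 0)
  expect_true(all(is.na(grid_values(mask_livestock_grazing(au, all_false)))))
  # stacks are masked layer-wise
  masked_stack <- mask_livestock_grazing(sc$inputs$npp, all_false)
  expect_true(all(is.na(stack_matrix(masked_stack))))
})
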