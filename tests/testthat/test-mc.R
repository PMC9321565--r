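test_that("truncated-normal draws respect their bounds and stated mean", {
  spec <- default_param_specs()$intake
  d <- sample_parameter(spec, 1000, seed = 1)
  expect_true(all(d >= 0.018 & d <= 0.04))
  big <- sample_parameter(spec, 1e5, seed = 2)
  mo <- spec_moments(spec)
  se <- mo["sd"] / sqrt(length(big))
  expect_lt(abs(mean(big) - 0.02), 3 * se)
  # the closed-form truncated moments agree with a numerical-integration
  # oracle
  mu <- grasscc:::truncnorm_location(0.02, spec$sd, 0.018, 0.04)
  z <- integrate(function(x) dnorm(x, mu, spec$sd), 0.018, 0.04)$value
  m_num <- integrate(function(x) x * dnorm(x, mu, spec$sd) / z,
                     0.018, 0.04)$value
  expect_equal(unname(mo["mean"]), m_num, tolerance = 1e-6)
})

test_that("uniform (mean, sd) specs span mean +/- sqrt(3) sd", {
  spec <- param_spec("npp", "uniform", mean = 1, sd = 0.07)
  expect_equal(spec$lower, 1 - sqrt(3) * 0.07, tolerance = 1e-12)
  expect_equal(spec$upper, 1 + sqrt(3) * 0.07, tolerance = 1e-12)
  expect_equal(c(spec$lower, spec$upper), c(0.8788, 1.1212),
               tolerance = 1e-4)
  d <- sample_parameter(spec, 5000, seed = 3)
  expect_true(all(d >= spec$lower & d <= spec$upper))
  expect_lt(abs(mean(d) - 1), 0.005)
  # the allocation-fraction factor uses sd 0.198 * 0.71
  f <- default_param_specs()$fanpp
  expect_equal(f$upper - f$lower, 2 * sqrt(3) * 0.14058, tolerance = 1e-9)
})

test_that("inconsistent specs are refused, degenerate specs are exact", {
  expect_error(param_spec("x", "truncated_normal", lower = 0, upper = 1,
                          mean = 2), "outside")
  expect_error(param_spec("x", "truncated_normal", lower = 1, upper = 0),
               "lower")
  expect_error(param_spec("x", "uniform"), "bounds")
  dg <- param_spec("x", "truncated_normal", lower = 0.5, upper = 0.5)
  expect_equal(sample_parameter(dg, 10, seed = 1), rep(0.5, 10))
})

test_that("draws are reproducible per seed and differ across seeds", {
  spec <- default_param_specs()$carbon
  expect_identical(sample_parameter(spec, 100, seed = 7),
                   sample_parameter(spec, 100, seed = 7))
  expect_false(identical(sample_parameter(spec, 100, seed = 7),
                         sample_parameter(spec, 100, seed = 8)))
})

test_that("ensemble CV matches hand computation and is scale invariant", {
  expect_equal(ensemble_cv(matrix(c(8, 12), 1, 2))[1], 100 * sd(c(8, 12)) / 10)
  expect_equal(ensemble_cv(matrix(c(8, 12), 1, 2))[1], 28.28, tolerance = 1e-3)
  expect_equal(ensemble_cv(matrix(5, 1, 3))[1], 0)
  m <- matrix(rlnorm(200), 20, 10)
  expect_equal(ensemble_cv(m * 3.3), ensemble_cv(m), tolerance = 1e-12)
  expect_true(is.na(ensemble_cv(matrix(c(-1, 1), 1, 2))[1]))
  expect_error(ensemble_cv(matrix(1, 2, 1)), "2 draws")
})

test_that("degenerate parameter specs give zero CV everywhere", {
  sc <- tiny_scenario(seed = 37)
  out <- propagate(list(npp = stack_layer(sc$inputs$npp, index = 8),
                        mat = sc$inputs$mat, canopy = sc$inputs$canopy,
                        slope = sc$inputs$slope, heads = sc$inputs$heads),
                   specs = degenerate_specs(), n = 50, seed = 1)
  for (v in c("agb", "cc", "rsd")) {
    cv <- grid_values(out[[v]]$cv)
    expect_true(all(abs(cv[!is.na(cv)]) < 1e-9), label = v)
  }
})

test_that("ensemble summaries are deterministic and medians lie in the envelope", {
  sc <- tiny_scenario(seed = 41)
  inp <- list(npp = stack_layer(sc$inputs$npp, index = 8),
              mat = sc$inputs$mat, canopy = sc$inputs$canopy,
              slope = sc$inputs$slope, heads = sc$inputs$heads)
  a <- propagate(inp, n = 100, seed = 5)
  b <- propagate(inp, n = 100, seed = 5)
  expect_identical(grid_values(a$cc$median), grid_values(b$cc$median))
  expect_identical(grid_values(a$rsd$cv), grid_values(b$rsd$cv))
  # envelope: reconstruct the draw factors from the same stream
  set.seed(5)
  draws <- lapply(default_param_specs(), sample_parameter, n = 100)
  k <- draws$npp * draws$fanpp / draws$carbon
  agb_pt <- grid_values(compute_agb(inp$npp, inp$mat, inp$canopy, inp$slope,
                                    agb_params(carbon_factor = 1 - 1e-15)))
  med <- grid_values(a$agb$median)
  ok <- which(!is.na(med) & !is.na(agb_pt))
  expect_true(all(med[ok] >= agb_pt[ok] * min(k) - 1e-9))
  expect_true(all(med[ok] <= agb_pt[ok] * max(k) + 1e-9))
})

test_that("a single draw's median map equals that draw", {
  sc <- tiny_scenario(seed = 43)
  inp <- list(npp = stack_layer(sc$inputs$npp, index = 8),
              mat = sc$inputs$mat, canopy = sc$inputs$canopy,
              slope = sc$inputs$slope)
  out <- propagate(inp, n = 1, seed = 9)
  set.seed(9)
  draws <- lapply(default_param_specs(), sample_parameter, n = 1)
  expected <- grid_values(compute_agb(inp$npp, inp$mat, inp$canopy,
                                      inp$slope)) *
    draws$npp * draws$fanpp * 0.475 / draws$carbon
  expect_equal(grid_values(out$agb$median), expected, tolerance = 1e-12)
})

test_that("intake-only uncertainty transfers the scalar 1/intake CV to CC", {
  sc <- tiny_scenario(seed = 47)
  specs <- degenerate_specs()
  specs$intake <- default_param_specs()$intake
  out <- propagate(list(npp = stack_layer(sc$inputs$npp, index = 8),
                        mat = sc$inputs$mat, canopy = sc$inputs$canopy,
                        slope = sc$inputs$slope),
                   specs = specs, n = 400, seed = 11)
  set.seed(11)
  draws <- lapply(specs, sample_parameter, n = 400)
  scalar_cv <- 100 * sd(1 / draws$intake) / mean(1 / draws$intake)
  cv <- grid_values(out$cc$cv)
  cv <- cv[!is.na(cv) & grid_values(out$cc$median) > 0]
  expect_true(all(abs(cv - scalar_cv) < 1e-6))
})

test_that("widening a spec never decreases the CC coefficient of variation", {
  widths <- c(0.002, 0.01, 0.022)
  cvs <- vapply(widths, function(w) {
    specs <- degenerate_specs()
    specs$intake <- param_spec("intake", "truncated_normal",
                               lower = 0.029 - w / 2, upper = 0.029 + w / 2)
    d <- sample_parameter(specs$intake, 2000, seed = 13)
    100 * sd(1 / d) / mean(1 / d)
  }, numeric(1))
  expect_true(all(diff(cvs) > 0))
})
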