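# independent oracles and small fixtures shared across tests

g1 <- function(x) raster_grid(matrix(x, 1, 1))

# brute-force Kendall tau-b by pair enumeration (independent of cor.test)
tau_brute <- function(x, y = seq_along(x)) {
  n <- length(x)
  conc <- disc <- 0
  tie_x <- tie_y <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
      if (sx == 0) tie_x <- tie_x + 1
      if (sy == 0) tie_y <- tie_y + 1
      if (sx != 0 && sy != 0) {
        if (sx == sy) conc <- conc + 1 else disc <- disc + 1
      }
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tie_x) * (n0 - tie_y))
}

# per-pixel scalar-loop AGB/CC/RSD oracle (no vectorized grid arithmetic)
scalar_chain_oracle <- function(npp, mat, canopy, slope, heads,
                                carbon = 0.475, intake = 0.02) {
  st <- slope_reclass_table()
  factors <- au_factor_table()
  nr <- nrow(grid_values(npp)); nc <- ncol(grid_values(npp))
  agb <- cc <- r <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      np <- grid_values(npp)[i, j]; tm <- grid_values(mat)[i, j]
      cn <- grid_values(canopy)[i, j]; sl <- grid_values(slope)[i, j]
      if (is.na(np) || is.na(tm) || is.na(cn) || is.na(sl)) next
      f <- 0.171 + 0.0129 * tm
      if (f <= 0) next
      mult <- NA_real_
      for (k in seq_len(nrow(st))) {
        if (sl <= st$upper[k]) { mult <- st$multiplier[k]; break }
      }
      agb[i, j] <- np * f / carbon * exp(-4.45521 * cn) * mult
      cc[i, j] <- agb[i, j] * 1000 / (455 * intake * 365)
      au_ij <- 0
      for (s in seq_len(nrow(factors))) {
        au_ij <- au_ij +
          grid_values(heads[[factors$species[s]]])[i, j] * factors$point[s]
      }
      r[i, j] <- if (cc[i, j] == 0 && au_ij > 0) Inf else
        if (cc[i, j] == 0) NA_real_ else au_ij / cc[i, j]
    }
  }
  list(agb = agb, cc = cc, rsd = r)
}

# closed-form OLS slope on one series
ols_slope_oracle <- function(t, y) {
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

# every uncertainty spec collapsed to its point value
degenerate_specs <- function() {
  specs <- default_param_specs()
  lapply(specs, function(s) {
    mo <- spec_moments(s)
    param_spec(s$name, "truncated_normal", lower = mo[["mean"]],
               upper = mo[["mean"]])
  })
}

tiny_scenario <- function(rows = 16, cols = 16, seed = 11, ...) {
  generate_scenario(scenario_config(rows = rows, cols = cols,
                                    seed = seed, ...))
}
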