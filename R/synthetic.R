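#' Configuration of a synthetic grassland scenario
#'
#' Describes a complete, internally consistent synthetic input bundle with
#' the statistical structure the analysis assumes: a spatially smooth
#' positive NPP field with a per-pixel linear trend and multiplicative
#' lognormal interannual noise,
#' `NPP(x, y, t) = base(x, y) * (1 + beta(x, y) * t) * eps_t`,
#' `eps_t ~ lognormal(0, sigma^2)` i.i.d. per year; a correlated
#' mean-annual-temperature field with a south-to-north gradient; canopy and
#' slope fields on their physical ranges; an IGBP class mosaic with an exact
#' grassland fraction; per-species livestock headcounts constructed so the
#' implied stocking ratios bracket the low/medium/overstocked classes; and a
#' livestock-production-system mask.
#'
#' @param rows,cols Grid dimensions.
#' @param years Calendar years of the stack.
#' @param seed RNG seed; the whole bundle is deterministic given the config.
#' @param npp_mean Spatial mean of base NPP (g C m-2 yr-1); must be > 0.
#' @param npp_spatial_cv Spatial coefficient of variation of the lognormal
#'   base field.
#' @param smoothness Half-width (cells) of the separable moving-average
#'   smoother applied to white noise to create spatial autocorrelation.
#' @param beta_mean,beta_sd Mean and spatial sd of the relative trend field
#'   (fraction per year).
#' @param sigma Lognormal sigma of the interannual noise (0 = noise-free).
#' @param mat_mean Mean annual temperature (degrees C) at mid-domain.
#' @param mat_gradient Temperature difference (degrees C) from the northern
#'   to the southern edge (north colder).
#' @param mat_noise_sd Sd of the smooth MAT anomaly field.
#' @param canopy_mean,canopy_sd Canopy-cover field parameters; clamped to
#'   `[0, 1]`.
#' @param slope_mean,slope_sd Terrain-slope field parameters (%); clamped to
#'   `>= 0`.
#' @param grassland_fraction Exact fraction of cells assigned a grass-bearing
#'   class, in `(0, 1]`.
#' @param grass_classes,filler_classes IGBP codes used for grassland and
#'   non-grassland cells.
#' @param lc_flip_rate Per-pixel-per-year probability that the land-cover
#'   layer shows a spurious other class (capped so the modal class always
#'   equals the assigned one).
#' @param class_fractions Named fractions (`low`, `medium`, `overstocked`)
#'   of eligible pixels assigned to each stocking-pressure class.
#' @param rsd_target_ranges List of length-2 ranges the per-pixel target
#'   stocking ratios are drawn from, one per class; kept clear of the
#'   0.20/0.65 boundaries so the construction is unambiguous.
#' @param grazing_fraction Fraction of cells inside the livestock-grazing
#'   production-system mask.
#' @param background_au Scale (AU km-2) of headcounts on pixels outside the
#'   eligible grassland/grazing area.
#' @param zones_dim Dimensions of the rectangular zone mosaic used for zonal
#'   statistics (e.g. `c(2, 2)` = four quadrants).
#' @param cellsize,crs Grid geometry (map units are km so that densities are
#'   per km2).
#' @export
scenario_config <- function(rows = 32, cols = 32, years = 2001:2015,
                            seed = 42,
                            npp_mean = 250, npp_spatial_cv = 0.3,
                            smoothness = 3,
                            beta_mean = 0, beta_sd = 0.01,
                            sigma = 0.1,
                            mat_mean = 10, mat_gradient = 10,
                            mat_noise_sd = 1,
                            canopy_mean = 0.15, canopy_sd = 0.15,
                            slope_mean = 8, slope_sd = 10,
                            grassland_fraction = 0.7,
                            grass_classes = c(8, 9, 10),
                            filler_classes = c(7, 12, 13, 16),
                            lc_flip_rate = 0.03,
                            class_fractions = c(low = 0.40, medium = 0.30,
                                                overstocked = 0.30),
                            rsd_target_ranges = list(
                              low = c(0.02, 0.17),
                              medium = c(0.25, 0.60),
                              overstocked = c(0.70, 1.50)),
                            grazing_fraction = 0.7,
                            background_au = 2,
                            zones_dim = c(2, 2),
                            cellsize = 1, crs = "local-km") {
  if (npp_mean <= 0) stop("base NPP mean must be positive")
  # YAML round trips deliver named maps as lists; coerce back
  class_fractions <- unlist(class_fractions)
  rsd_target_ranges <- lapply(rsd_target_ranges, unlist)
  zones_dim <- unlist(zones_dim)
  stopifnot(rows >= 2, cols >= 2, length(years) >= 2,
            grassland_fraction > 0, grassland_fraction <= 1,
            sigma >= 0, canopy_sd >= 0, slope_sd >= 0,
            grazing_fraction >= 0, grazing_fraction <= 1)
  stopifnot(abs(sum(class_fractions) - 1) < 1e-8)
  structure(as.list(environment()), class = "scenario_config")
}

# separable moving-average smoothing of white noise, standardised to
# mean 0 / sd 1 -- the simplest controllable spatial autocorrelation
smooth_field <- function(nr, nc, w) {
  pad <- w
  z <- matrix(stats::rnorm((nr + 2 * pad) * (nc + 2 * pad)),
              nr + 2 * pad, nc + 2 * pad)
  if (w > 0) {
    k <- rep(1 / (2 * w + 1), 2 * w + 1)
    z <- apply(z, 2, function(col) stats::filter(col, k, sides = 2))
    z <- t(apply(z, 1, function(row) stats::filter(row, k, sides = 2)))
  }
  z <- z[pad + seq_len(nr), pad + seq_len(nc), drop = FALSE]
  (z - mean(z)) / stats::sd(z)
}

#' Generate a synthetic scenario
#'
#' Builds the full input bundle (NPP stack, MAT, canopy, slope, land-cover
#' stack, species headcounts, production-system mask, zone mosaic) plus the
#' ground truth it was constructed from (trend field, noise-free NPP,
#' animal-unit density, stocking-pressure class labels). Deterministic for a
#' fixed config (which includes the seed).
#'
#' @param config A [scenario_config()].
#' @return A list of class `cc_scenario` with elements `inputs` and `truth`.
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  cf <- config
  set.seed(cf$seed)
  nr <- cf$rows; nc <- cf$cols; n <- nr * nc
  yrs <- as.integer(cf$years); nt <- length(yrs)
  template <- raster_grid(matrix(0, nr, nc), cellsize = cf$cellsize,
                          crs = cf$crs)
  as_grid <- function(v) grid_set_values(template, v)

  # base NPP: lognormal around npp_mean with spatial CV
  sdlog <- sqrt(log(1 + cf$npp_spatial_cv^2))
  z_base <- smooth_field(nr, nc, cf$smoothness)
  base <- cf$npp_mean * exp(sdlog * z_base - sdlog^2 / 2)

  # relative trend field (fraction per year)
  beta <- cf$beta_mean + cf$beta_sd * smooth_field(nr, nc, cf$smoothness)

  t_idx <- seq_len(nt) - 1
  clean <- vapply(t_idx, function(t) as.vector(base * (1 + beta * t)),
                  numeric(n))
  if (any(clean <= 0)) {
    stop("trend drives NPP non-positive; reduce |beta| or the time span")
  }
  eps <- if (cf$sigma > 0) {
    matrix(stats::rlnorm(n * nt, meanlog = 0, sdlog = cf$sigma), n, nt)
  } else {
    matrix(1, n, nt)
  }
  npp_stack <- matrix_stack(clean * eps, yrs, template)

  # temperature: latitudinal gradient (row 1 = north = coldest) + anomaly
  row_frac <- (row(matrix(0, nr, nc)) - 0.5) / nr
  mat <- cf$mat_mean + cf$mat_gradient * (row_frac - 0.5) +
    cf$mat_noise_sd * smooth_field(nr, nc, cf$smoothness)

  canopy <- pmin(1, pmax(0, cf$canopy_mean +
                           cf$canopy_sd * smooth_field(nr, nc, cf$smoothness)))
  slope <- pmax(0, cf$slope_mean +
                  cf$slope_sd * smooth_field(nr, nc, cf$smoothness))

  # land cover: exact grassland fraction by rank selection
  z_lc <- smooth_field(nr, nc, cf$smoothness)
  n_grass <- max(1L, round(cf$grassland_fraction * n))
  grass_idx <- order(as.vector(z_lc), decreasing = TRUE)[seq_len(n_grass)]
  is_grass <- rep(FALSE, n); is_grass[grass_idx] <- TRUE
  base_class <- rep(NA_real_, n)
  # split grassland cells into the grass-bearing classes by rank tertiles
  splits <- ceiling(seq_along(grass_idx) * length(cf$grass_classes) /
                      length(grass_idx))
  base_class[grass_idx] <- cf$grass_classes[splits]
  base_class[!is_grass] <- sample(cf$filler_classes, n - n_grass,
                                  replace = TRUE)

  # annual layers: mostly the base class, with spurious flips capped so the
  # mode always recovers the base class
  all_classes <- c(cf$grass_classes, cf$filler_classes)
  lc <- matrix(rep(base_class, nt), n, nt)
  flips <- matrix(stats::runif(n * nt) < cf$lc_flip_rate, n, nt)
  max_flips <- (nt - 1L) %/% 2L
  for (i in which(rowSums(flips) > 0)) {
    js <- which(flips[i, ])
    if (length(js) > max_flips) js <- js[seq_len(max_flips)]
    alt <- setdiff(all_classes, base_class[i])
    lc[i, js] <- sample(alt, length(js), replace = TRUE)
  }
  lc_stack <- matrix_stack(lc, yrs, template)

  # livestock-grazing production-system mask (exact fraction)
  z_sys <- smooth_field(nr, nc, cf$smoothness)
  n_graz <- round(cf$grazing_fraction * n)
  graz <- rep(0, n)
  graz[order(as.vector(z_sys), decreasing = TRUE)[seq_len(n_graz)]] <- 1

  # zone mosaic
  zr <- ceiling(row(matrix(0, nr, nc)) / (nr / cf$zones_dim[1]))
  zc <- ceiling(col(matrix(0, nr, nc)) / (nc / cf$zones_dim[2]))
  zones <- (zr - 1) * cf$zones_dim[2] + zc

  # reference-year carrying capacity, computed with plain scalar arithmetic
  ref_i <- ceiling(nt / 2)
  npp_ref <- as.vector(grid_values(stack_layer(npp_stack, index = ref_i)))
  f <- 0.171 + 0.0129 * as.vector(mat)
  f[f <= 0] <- NA_real_
  sm_tab <- slope_reclass_table()
  sm <- sm_tab$multiplier[findInterval(as.vector(slope), c(-Inf, sm_tab$upper),
                                       left.open = TRUE)]
  agb_ref <- npp_ref * f / 0.475 * exp(-4.45521 * as.vector(canopy)) * sm
  cc_ref <- agb_ref * 1000 / (455 * 0.02 * 365)

  # stocking construction: stratified target ratios on eligible pixels
  eligible <- is_grass & graz == 1 & is.finite(cc_ref) & cc_ref > 0
  elig_idx <- sample(which(eligible))
  n_e <- length(elig_idx)
  counts <- round(cf$class_fractions * n_e)
  counts[length(counts)] <- n_e - sum(counts[-length(counts)])
  cls_truth <- rep(NA_real_, n)
  target <- rep(NA_real_, n)
  pos <- 0
  for (k in seq_along(counts)) {
    idx_k <- elig_idx[pos + seq_len(counts[k])]
    pos <- pos + counts[k]
    rng <- cf$rsd_target_ranges[[k]]
    cls_truth[idx_k] <- k
    target[idx_k] <- stats::runif(length(idx_k), rng[1], rng[2])
  }
  au <- rep(NA_real_, n)
  au[eligible] <- target[eligible] * cc_ref[eligible]
  au[!eligible] <- cf$background_au * stats::rgamma(sum(!eligible), shape = 1)

  # split AU density across species via gamma-field weights, so the point
  # animal-unit conversion reproduces the AU density exactly
  factors <- au_factor_table()
  w <- matrix(stats::rgamma(n * nrow(factors), shape = 2), n)
  w <- w / rowSums(w)
  heads <- lapply(seq_len(nrow(factors)), function(s) {
    as_grid(au * w[, s] / factors$point[s])
  })
  names(heads) <- factors$species

  structure(list(
    inputs = list(
      npp = npp_stack, mat = as_grid(mat), canopy = as_grid(canopy),
      slope = as_grid(slope), landcover = lc_stack, heads = heads,
      grazing_mask = as_grid(graz), zones = as_grid(as.vector(zones))
    ),
    truth = list(
      beta = as_grid(beta), base_npp = as_grid(as.vector(base)),
      npp_clean = matrix_stack(clean, yrs, template),
      au_density = as_grid(au), rsd_target = as_grid(target),
      rsd_class = as_grid(cls_truth), grassland = as_grid(as.numeric(is_grass)),
      cc_reference = as_grid(cc_ref), reference_year = yrs[ref_i],
      config = config
    )
  ), class = "cc_scenario")
}

#' Write a scenario's input bundle to a fixture directory
#'
#' Writes every input layer in the package's text raster formats, plus a
#' `scenario.yml` recording the generating configuration (including the
#' seed), from which the bundle can be regenerated byte-identically.
#'
#' @param scenario A `cc_scenario` from [generate_scenario()].
#' @param dir Output directory (created if needed).
#' @param digits Formatting precision for the raster writer.
#' @export
write_fixture <- function(scenario, dir, digits = 6) {
  stopifnot(inherits(scenario, "cc_scenario"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  inp <- scenario$inputs
  write_stack(inp$npp, dir, "npp", digits = digits)
  write_stack(inp$landcover, dir, "landcover", digits = digits)
  write_grid(inp$mat, file.path(dir, "mat.asc"), digits = digits)
  write_grid(inp$canopy, file.path(dir, "canopy.asc"), digits = digits)
  write_grid(inp$slope, file.path(dir, "slope.asc"), digits = digits)
  write_grid(inp$grazing_mask, file.path(dir, "grazing_mask.asc"),
             digits = digits)
  write_grid(inp$zones, file.path(dir, "zones.asc"), digits = digits)
  for (sp in names(inp$heads)) {
    write_grid(inp$heads[[sp]], file.path(dir, sprintf("heads_%s.asc", sp)),
               digits = digits)
  }
  cfg <- scenario$truth$config
  yaml::write_yaml(cfg[setdiff(names(cfg), "")], file.path(dir, "scenario.yml"))
  invisible(dir)
}

#' Read a fixture directory written by [write_fixture()]
#' @param dir Fixture directory.
#' @return A list with the same `inputs` structure as a generated scenario,
#'   plus the recorded `scenario.yml` configuration under `config`.
#' @export
read_fixture <- function(dir) {
  heads_files <- list.files(dir, pattern = "^heads_.*\\.asc$")
  heads <- lapply(heads_files, function(f) read_grid(file.path(dir, f)))
  names(heads) <- sub("^heads_(.*)\\.asc$", "\\1", heads_files)
  cfg_path <- file.path(dir, "scenario.yml")
  config <- if (file.exists(cfg_path)) {
    do.call(scenario_config, yaml::read_yaml(cfg_path))
  }
  list(inputs = list(
    npp = read_stack(dir, "npp"),
    mat = read_grid(file.path(dir, "mat.asc")),
    canopy = read_grid(file.path(dir, "canopy.asc")),
    slope = read_grid(file.path(dir, "slope.asc")),
    landcover = read_stack(dir, "landcover"),
    heads = heads,
    grazing_mask = read_grid(file.path(dir, "grazing_mask.asc")),
    zones = read_grid(file.path(dir, "zones.asc"))
  ), config = config)
}
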