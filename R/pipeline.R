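#' Run configuration
#'
#' Declarative description of a full pipeline run. Inputs come either from a
#' synthetic scenario (`scenario`, a [scenario_config()] or a list of its
#' arguments) or from a fixture directory (`input_dir`). All model
#' parameters are overridable here; unset entries take the package defaults.
#'
#' @param scenario Optional [scenario_config()] (or argument list) to
#'   simulate inputs.
#' @param input_dir Optional fixture directory readable by [read_fixture()].
#' @param years Years to analyse (default: all years of the NPP stack).
#' @param window_years Reference window for the stocking-density maps
#'   (default: the five years centred on the stack midpoint).
#' @param n_draws Monte-Carlo draws (default 1000).
#' @param rng_seed Seed controlling simulation and Monte Carlo.
#' @param class_thresholds Length-2 vector `(low_max, med_max)`, default
#'   `c(0.20, 0.65)`.
#' @param agb_floor Display mask: output maps are masked to cells with AGB
#'   above this value (g m-2 yr-1, default 0.1).
#' @param alpha Significance level of the pixel trend mask.
#' @param agb AGB model parameters, [agb_params()].
#' @param au Animal-unit parameters, [animal_unit_params()].
#' @param specs Uncertainty specifications, [default_param_specs()].
#' @param grass_classes IGBP codes treated as grassland.
#' @param out_dir Optional output directory; when set, [run_pipeline()]
#'   writes every product plus a manifest there.
#' @param quiet Suppress stage-by-stage log messages.
#' @export
run_config <- function(scenario = NULL, input_dir = NULL, years = NULL,
                       window_years = NULL, n_draws = 1000, rng_seed = 1,
                       class_thresholds = c(0.20, 0.65), agb_floor = 0.1,
                       alpha = 0.05, agb = agb_params(),
                       au = animal_unit_params(),
                       specs = default_param_specs(),
                       grass_classes = c(8, 9, 10),
                       out_dir = NULL, quiet = FALSE) {
  stopifnot(n_draws >= 1)
  class_thresholds <- unlist(class_thresholds)
  stopifnot(length(class_thresholds) == 2, 0 < class_thresholds[1],
            class_thresholds[1] < class_thresholds[2])
  if (is.list(scenario) && !inherits(scenario, "scenario_config")) {
    scenario <- do.call(scenario_config, scenario)
  }
  if (is.list(agb) && !inherits(agb, "agb_params")) {
    if (!is.null(agb$slope_table) && !tibble::is_tibble(agb$slope_table)) {
      st <- lapply(agb$slope_table, unlist)
      st$upper[!is.finite(st$upper)] <- Inf
      agb$slope_table <- do.call(slope_reclass_table, st)
    }
    agb <- do.call(agb_params, agb)
  }
  if (is.list(au) && !inherits(au, "animal_unit_params")) {
    au <- do.call(animal_unit_params, au)
  }
  # a partial specs list (e.g. from a config file) overrides the defaults
  specs <- local({
    given <- lapply(stats::setNames(names(specs), names(specs)), function(nm) {
      el <- specs[[nm]]
      if (inherits(el, "param_spec")) el else
        do.call(param_spec, c(list(name = nm), el))
    })
    full <- default_param_specs()
    full[names(given)] <- given
    full
  })
  structure(as.list(environment()), class = "run_config")
}

default_window <- function(years) {
  mid <- ceiling(length(years) / 2)
  years[pmax(1, mid - 2):pmin(length(years), mid + 2)]
}

#' Run the full carrying-capacity pipeline
#'
#' Chains every stage on one configuration: input acquisition (simulation or
#' fixture), harmonization to the NPP geometry, land-cover mode compositing
#' and grassland masking, per-year AGB and carrying capacity, animal-unit
#' conversion, relative stocking density (reference-window median, minimum-CC
#' and overstocked-year-share variants) with pressure classification and
#' livestock-grazing masking, per-pixel trend and variability statistics,
#' Monte-Carlo uncertainty summaries over the reference window, and zonal
#' tables. Deterministic for a fixed configuration (seed included).
#'
#' @param config A [run_config()] (or a list of its arguments).
#' @return A list of class `cc_run` holding all products and a `manifest`
#'   tibble enumerating them; when `out_dir` is configured every product is
#'   also written to disk and the manifest gains the file paths.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  cf <- config
  quiet <- isTRUE(cf$quiet)

  truth <- NULL
  if (!is.null(cf$scenario)) {
    log_stage(quiet, "simulate: %d x %d cells, %d years",
              cf$scenario$rows, cf$scenario$cols, length(cf$scenario$years))
    scen <- generate_scenario(cf$scenario)
    inputs <- scen$inputs
    truth <- scen$truth
  } else if (!is.null(cf$input_dir)) {
    log_stage(quiet, "read inputs from %s", cf$input_dir)
    inputs <- read_fixture(cf$input_dir)$inputs
  } else {
    stop("config must provide either a scenario or an input_dir")
  }

  ref <- stack_layer(inputs$npp, index = 1)
  harmonize <- function(g, kind) {
    if (same_geometry(g, ref)) g else resample_to_reference(g, ref, kind)
  }
  inputs$mat <- harmonize(inputs$mat, "continuous")
  inputs$canopy <- harmonize(inputs$canopy, "continuous")
  inputs$slope <- harmonize(inputs$slope, "continuous")
  inputs$grazing_mask <- harmonize(inputs$grazing_mask, "categorical")
  inputs$zones <- harmonize(inputs$zones, "categorical")
  inputs$heads <- lapply(inputs$heads, harmonize, kind = "continuous")
  inputs$landcover <- stack_map(inputs$landcover, harmonize,
                                kind = "categorical")

  years <- if (is.null(cf$years)) stack_years(inputs$npp) else
    as.integer(cf$years)
  npp <- stack_subset(inputs$npp, years)
  window_years <- if (is.null(cf$window_years)) default_window(years) else
    intersect(as.integer(cf$window_years), years)

  n_cells <- prod(dim(ref))
  lc_mode <- mode_landcover(inputs$landcover)
  grass <- grassland_mask(lc_mode, cf$grass_classes)
  n_grass <- sum(grid_values(grass) == 1, na.rm = TRUE)
  log_stage(quiet, "grassland mask: %d / %d cells retained", n_grass, n_cells)

  agb_stack <- compute_agb_stack(npp, inputs$mat, inputs$canopy,
                                 inputs$slope, cf$agb, mask = grass)
  n_agb <- sum(!is.na(grid_values(stack_layer(agb_stack, index = 1))))
  log_stage(quiet, "AGB: %d cells defined (cold/nodata exclusions: %d)",
            n_agb, n_grass - n_agb)
  cc_stack <- carrying_capacity_stack(agb_stack, cf$au)
  au <- animal_units(inputs$heads)

  scheme <- rsd_class_scheme(cf$class_thresholds[1], cf$class_thresholds[2])
  # display mask: AGB above the floor in the median window year
  agb_med <- grid_set_values(ref, row_median(stack_matrix(
    stack_subset(agb_stack, window_years))))
  display <- grid_map(agb_med, function(v) as.numeric(v > cf$agb_floor))
  graze_mask <- inputs$grazing_mask

  finish <- function(g) mask_livestock_grazing(g, display)
  rsd_median <- finish(median_rsd_window(au, cc_stack, window_years))
  rsd_min <- finish(rsd_min_cc(au, cc_stack))
  rsd_classes <- classify_rsd(rsd_median, scheme)
  over_frac <- finish(overstocked_year_fraction(au, cc_stack, scheme))
  rsd_grazing <- mask_livestock_grazing(rsd_median, graze_mask)
  cc_grazing <- mask_livestock_grazing(
    stack_layer(cc_stack, index = ceiling(length(years) / 2)), graze_mask)
  log_stage(quiet, "RSD: %d cells in display mask, %d in grazing systems",
            sum(grid_values(display) == 1, na.rm = TRUE),
            sum(!is.na(grid_values(rsd_grazing))))

  trend <- pixel_trend(cc_stack, alpha = cf$alpha)
  cv_iv <- interannual_cv(cc_stack)
  mmr <- min_median_ratio(cc_stack)

  log_stage(quiet, "Monte Carlo: %d draws x %d window years",
            cf$n_draws, length(window_years))
  mc_years <- lapply(seq_along(window_years), function(i) {
    propagate(list(npp = stack_layer(npp, year = window_years[i]),
                   mat = inputs$mat, canopy = inputs$canopy,
                   slope = inputs$slope, heads = inputs$heads,
                   mask = grass),
              specs = cf$specs, n = cf$n_draws, seed = cf$rng_seed + i,
              params = cf$agb)
  })
  combine <- function(var, what) {
    grid_set_values(ref, row_median(vapply(mc_years, function(m) {
      as.vector(grid_values(m[[var]][[what]]))
    }, numeric(n_cells))))
  }
  mc <- list(
    agb = list(median = combine("agb", "median"), cv = combine("agb", "cv")),
    cc = list(median = combine("cc", "median"), cv = combine("cc", "cv")),
    rsd = list(median = combine("rsd", "median"), cv = combine("rsd", "cv")),
    n_draws = cf$n_draws, window_years = window_years
  )

  zonal_cc <- zonal_summary(cc_stack, inputs$zones, "sum")
  zonal_tr <- zonal_trend(zonal_cc)
  class_tab <- rsd_class_table(rsd_classes, scheme)

  results <- list(
    landcover_mode = lc_mode, grassland = grass, agb = agb_stack,
    cc = cc_stack, au = au, rsd_median = rsd_median, rsd_min_cc = rsd_min,
    rsd_classes = rsd_classes, overstocked_fraction = over_frac,
    rsd_grazing = rsd_grazing, cc_grazing = cc_grazing, trend = trend,
    interannual_cv = cv_iv, min_median_ratio = mmr, mc = mc,
    zonal_cc = zonal_cc, zonal_trend = zonal_tr, class_table = class_tab,
    window_years = window_years, truth = truth, config = cf
  )
  results$manifest <- build_manifest(results, cf$out_dir)
  if (!is.null(cf$out_dir)) write_outputs(results, cf$out_dir)
  structure(results, class = "cc_run")
}

manifest_entries <- function() {
  tibble::tribble(
    ~name, ~type, ~file,
    "landcover_mode", "grid", "landcover_mode.asc",
    "grassland", "grid", "grassland.asc",
    "agb", "stack", "agb_years.csv",
    "cc", "stack", "cc_years.csv",
    "au", "grid", "au.asc",
    "rsd_median", "grid", "rsd_median.asc",
    "rsd_min_cc", "grid", "rsd_min_cc.asc",
    "rsd_classes", "grid", "rsd_classes.asc",
    "overstocked_fraction", "grid", "overstocked_fraction.asc",
    "rsd_grazing", "grid", "rsd_grazing.asc",
    "cc_grazing", "grid", "cc_grazing.asc",
    "trend_scaled_change", "grid", "trend_scaled_change.asc",
    "trend_p_value", "grid", "trend_p_value.asc",
    "interannual_cv", "grid", "interannual_cv.asc",
    "min_median_ratio", "grid", "min_median_ratio.asc",
    "mc_cc_median", "grid", "mc_cc_median.asc",
    "mc_cc_cv", "grid", "mc_cc_cv.asc",
    "mc_rsd_median", "grid", "mc_rsd_median.asc",
    "mc_rsd_cv", "grid", "mc_rsd_cv.asc",
    "zonal_cc", "table", "zonal_cc.csv",
    "zonal_trend", "table", "zonal_trend.csv",
    "class_table", "table", "class_table.csv"
  )
}

build_manifest <- function(results, out_dir) {
  m <- manifest_entries()
  if (is.null(out_dir)) m$file <- NA_character_ else
    m$file <- file.path(out_dir, m$file)
  m
}

write_outputs <- function(results, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wg <- function(g, f) write_grid(g, file.path(out_dir, f))
  wg(results$landcover_mode, "landcover_mode.asc")
  wg(results$grassland, "grassland.asc")
  write_stack(results$agb, out_dir, "agb")
  write_stack(results$cc, out_dir, "cc")
  wg(results$au, "au.asc")
  wg(results$rsd_median, "rsd_median.asc")
  wg(results$rsd_min_cc, "rsd_min_cc.asc")
  wg(results$rsd_classes, "rsd_classes.asc")
  wg(results$overstocked_fraction, "overstocked_fraction.asc")
  wg(results$rsd_grazing, "rsd_grazing.asc")
  wg(results$cc_grazing, "cc_grazing.asc")
  wg(results$trend$scaled_change, "trend_scaled_change.asc")
  wg(results$trend$p_value, "trend_p_value.asc")
  wg(results$interannual_cv, "interannual_cv.asc")
  wg(results$min_median_ratio, "min_median_ratio.asc")
  wg(results$mc$cc$median, "mc_cc_median.asc")
  wg(results$mc$cc$cv, "mc_cc_cv.asc")
  wg(results$mc$rsd$median, "mc_rsd_median.asc")
  wg(results$mc$rsd$cv, "mc_rsd_cv.asc")
  utils::write.csv(results$zonal_cc, file.path(out_dir, "zonal_cc.csv"),
                   row.names = FALSE)
  utils::write.csv(results$zonal_trend, file.path(out_dir, "zonal_trend.csv"),
                   row.names = FALSE)
  utils::write.csv(results$class_table, file.path(out_dir, "class_table.csv"),
                   row.names = FALSE)
  utils::write.csv(results$manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.cc_run <- function(x, ...) {
  cat(sprintf("<cc_run> %d years, %d MC draws, window %s\n",
              length(stack_years(x$cc)), x$mc$n_draws,
              paste(range(x$window_years), collapse = "-")))
  print(x$class_table)
  invisible(x)
}
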