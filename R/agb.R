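#' Parameters of the aboveground-biomass model
#'
#' Bundles the coefficients of the NPP-to-forage chain: the linear
#' temperature model for the aboveground allocation fraction
#' `f_ANPP = intercept + slope * MAT`, the exponential decay coefficient of
#' the tree-canopy transfer function, the biomass carbon fraction used to
#' convert NPP from carbon to dry-matter units, and the terrain-slope
#' reclassification table.
#'
#' @param fanpp_intercept Intercept of the allocation model (dimensionless).
#' @param fanpp_slope Temperature coefficient (per degree C).
#' @param tree_decay Decay coefficient of the canopy transfer function.
#' @param carbon_factor Carbon content of dry biomass (g C per g biomass).
#'   The point default 0.475 is the conventional biomass carbon fraction,
#'   inside the uncertainty interval [0.47, 0.50] used by the Monte Carlo.
#' @param slope_table A [slope_reclass_table()].
#' @export
agb_params <- function(fanpp_intercept = 0.171, fanpp_slope = 0.0129,
                       tree_decay = 4.45521, carbon_factor = 0.475,
                       slope_table = slope_reclass_table()) {
  stopifnot(carbon_factor > 0, carbon_factor < 1, tree_decay > 0)
  structure(list(fanpp_intercept = fanpp_intercept,
                 fanpp_slope = fanpp_slope,
                 tree_decay = tree_decay,
                 carbon_factor = carbon_factor,
                 slope_table = slope_table),
            class = "agb_params")
}

#' Terrain-slope reclassification table
#'
#' Step function mapping terrain slope (%) to a grazing-accessibility
#' multiplier in `[0, 1]`. A slope equal to a class upper bound belongs to
#' the lower (gentler) class. The default four-class scheme follows
#' rangeland-management recommendations: gentle terrain fully usable, usable
#' fraction dropping with steepness, terrain above 60% slope unusable.
#'
#' @param upper Strictly increasing upper bounds (%); last is `Inf`.
#' @param multiplier Non-increasing multipliers in `[0, 1]`.
#' @return A tibble with columns `upper`, `multiplier`.
#' @export
slope_reclass_table <- function(upper = c(10, 30, 60, Inf),
                                multiplier = c(1.0, 0.7, 0.4, 0.0)) {
  stopifnot(length(upper) == length(multiplier),
            all(diff(upper) > 0), all(diff(multiplier) <= 0),
            multiplier[1] <= 1, all(multiplier >= 0),
            is.infinite(upper[length(upper)]))
  tibble::tibble(upper = upper, multiplier = multiplier)
}

#' Aboveground allocation fraction from mean annual temperature
#'
#' Linear model `f_ANPP = 0.171 + 0.0129 * MAT` (MAT in degrees C) for the
#' fraction of net primary productivity allocated aboveground on grasslands.
#' Cells where the fraction is non-positive (MAT below about -13.26 C, the
#' exact root of the linear form) are excluded, i.e. set to nodata.
#'
#' @param mat `raster_grid` of mean annual temperature (degrees C).
#' @param params An [agb_params()].
#' @return `raster_grid` of fractions; nodata where `f_ANPP <= 0`.
#' @export
fanpp <- function(mat, params = agb_params()) {
  stopifnot(is_raster_grid(mat))
  f <- params$fanpp_intercept + params$fanpp_slope * grid_values(mat)
  f[f <= 0] <- NA_real_
  grid_set_values(mat, f)
}

#' Tree-canopy transfer function
#'
#' Fraction of productivity available to grazers under a tree canopy:
#' `exp(-k * x)` with `x` the canopy-cover fraction and decay `k = 4.45521`
#' by default. Equals 1 at zero cover and decays to about 0.012 at full
#' cover.
#'
#' @param canopy `raster_grid` of canopy-cover fraction in `[0, 1]`.
#' @param params An [agb_params()] (supplies `tree_decay`).
#' @export
tree_cover_multiplier <- function(canopy, params = agb_params()) {
  stopifnot(is_raster_grid(canopy))
  x <- grid_values(canopy)
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    stop("canopy cover must lie in [0, 1]")
  }
  grid_set_values(canopy, exp(-params$tree_decay * x))
}

#' Terrain-slope multiplier
#'
#' Looks each cell's slope (%) up in a [slope_reclass_table()]; a slope equal
#' to a class boundary takes the gentler class's multiplier.
#'
#' @param slope `raster_grid` of terrain slope in percent (`>= 0`).
#' @param table A [slope_reclass_table()].
#' @export
slope_multiplier <- function(slope, table = slope_reclass_table()) {
  stopifnot(is_raster_grid(slope))
  s <- grid_values(slope)
  if (any(s < 0, na.rm = TRUE)) stop("terrain slope must be non-negative")
  idx <- findInterval(s, c(-Inf, table$upper), left.open = TRUE)
  out <- table$multiplier[idx]
  out[is.na(s)] <- NA_real_
  grid_set_values(slope, out)
}

#' Aboveground biomass available for grazing
#'
#' Chains the full forage model:
#' `AGB = NPP * f_ANPP / carbon_factor * TreeCoverMultiplier * SlopeMultiplier`
#' giving dry biomass in g m-2 yr-1 from NPP in g C m-2 yr-1. Nodata wherever
#' any input is nodata or the allocation fraction is non-positive (cold-area
#' exclusion); optionally restricted to a grassland mask.
#'
#' @param npp `raster_grid` of annual NPP (g C m-2 yr-1).
#' @param mat `raster_grid` of mean annual temperature (degrees C).
#' @param canopy `raster_grid` of tree-canopy cover fraction.
#' @param slope `raster_grid` of terrain slope (%).
#' @param params An [agb_params()].
#' @param mask Optional boolean `raster_grid`; cells that are not `TRUE`
#'   become nodata.
#' @return `raster_grid` of AGB (g biomass m-2 yr-1).
#' @export
compute_agb <- function(npp, mat, canopy, slope, params = agb_params(),
                        mask = NULL) {
  for (g in list(mat, canopy, slope)) check_same_geometry(npp, g, "AGB inputs")
  agb <- npp * fanpp(mat, params) / params$carbon_factor *
    tree_cover_multiplier(canopy, params) *
    slope_multiplier(slope, params$slope_table)
  if (!is.null(mask)) agb <- mask_livestock_grazing(agb, mask)
  agb
}

#' AGB for every year of an NPP stack
#' @inheritParams compute_agb
#' @param npp_stack `annual_stack` of NPP layers.
#' @export
compute_agb_stack <- function(npp_stack, mat, canopy, slope,
                              params = agb_params(), mask = NULL) {
  stack_map(npp_stack, compute_agb, mat = mat, canopy = canopy,
            slope = slope, params = params, mask = mask)
}
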