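#' Animal-unit definition
#'
#' One animal unit (AU) is a 455 kg reference grazer whose daily dry-matter
#' intake is a fraction of its body weight; the intake fraction ranges from
#' 0.018 to 0.04 across animal classes and conditions, with 0.02 as the
#' point estimate.
#'
#' @param au_weight AU body weight in kg.
#' @param daily_intake_fraction Daily dry-matter intake as a fraction of body
#'   weight; must lie in `[0.018, 0.04]`.
#' @export
animal_unit_params <- function(au_weight = 455, daily_intake_fraction = 0.02) {
  stopifnot(au_weight > 0)
  if (daily_intake_fraction <= 0) stop("daily intake fraction must be > 0")
  if (daily_intake_fraction < 0.018 || daily_intake_fraction > 0.04) {
    stop("daily intake fraction must lie within [0.018, 0.04]")
  }
  structure(list(au_weight = au_weight,
                 daily_intake_fraction = daily_intake_fraction),
            class = "animal_unit_params")
}

#' Species-to-animal-unit conversion factor table
#'
#' Per-species conversion factors from headcounts to animal units, as
#' truncated-normal uncertainty intervals. The `point` column is the stated
#' mean where one exists (cattle) and the interval midpoint otherwise.
#'
#' @return A tibble with columns `species`, `lower`, `upper`, `point`.
#' @export
au_factor_table <- function() {
  tab <- tibble::tibble(
    species = c("cattle", "buffalo", "sheep", "goat", "horse"),
    lower   = c(0.50, 0.60, 0.10, 0.10, 0.40),
    upper   = c(1.25, 0.70, 0.15, 0.15, 1.80),
    point   = c(1.00, 0.65, 0.125, 0.125, 1.10)
  )
  stopifnot(all(tab$lower > 0), all(tab$lower < tab$upper))
  tab
}

#' Stocking-pressure classification scheme
#'
#' Relative stocking density classes bounded by the minimum (0.20) and
#' maximum (0.65) proper-use factors reported in the rangeland literature:
#' below `low_max` is low pressure, `[low_max, med_max]` medium pressure
#' (the printed interval is read as closed, so both boundaries classify as
#' medium), above `med_max` overstocked.
#'
#' @param low_max,med_max Class boundaries, `0 < low_max < med_max`.
#' @export
rsd_class_scheme <- function(low_max = 0.20, med_max = 0.65) {
  stopifnot(0 < low_max, low_max < med_max)
  structure(list(low_max = low_max, med_max = med_max,
                 labels = c("low pressure", "medium pressure", "overstocked")),
            class = "rsd_class_scheme")
}

#' Livestock carrying capacity from aboveground biomass
#'
#' `CC = AGB / (weight_AU * intake_daily * 365)` with AGB converted from
#' g m-2 yr-1 to kg km-2 yr-1 (factor 1000), giving the stocking an area's
#' forage can sustain in AU km-2 yr-1.
#'
#' @param agb `raster_grid` of AGB (g m-2 yr-1).
#' @param params An [animal_unit_params()].
#' @export
carrying_capacity <- function(agb, params = animal_unit_params()) {
  stopifnot(is_raster_grid(agb))
  agb * 1000 / (params$au_weight * params$daily_intake_fraction * 365)
}

#' Carrying capacity for every year of an AGB stack
#' @param agb_stack `annual_stack` of AGB layers.
#' @inheritParams carrying_capacity
#' @export
carrying_capacity_stack <- function(agb_stack, params = animal_unit_params()) {
  stack_map(agb_stack, carrying_capacity, params = params)
}

#' Convert species headcount densities to animal-unit density
#'
#' Weighted sum of per-species headcount layers (head km-2) with the species
#' conversion factors, giving AU km-2.
#'
#' @param heads Named list of `raster_grid` headcount layers; names must be
#'   species present in `factors`.
#' @param factors An [au_factor_table()] or compatible tibble.
#' @param at Either `"point"` (use the `point` column) or a named numeric
#'   vector of factors (one draw), e.g. from the Monte Carlo sampler.
#' @export
animal_units <- function(heads, factors = au_factor_table(), at = "point") {
  stopifnot(is.list(heads), length(heads) >= 1, !is.null(names(heads)))
  unknown <- setdiff(names(heads), factors$species)
  if (length(unknown)) {
    stop("unknown species: ", paste(unknown, collapse = ", "))
  }
  if (identical(at, "point")) {
    f <- stats::setNames(factors$point, factors$species)
  } else {
    stopifnot(is.numeric(at), all(names(heads) %in% names(at)))
    f <- at
  }
  out <- NULL
  for (sp in names(heads)) {
    h <- heads[[sp]]
    stopifnot(is_raster_grid(h))
    if (any(grid_values(h) < 0, na.rm = TRUE)) {
      stop("headcounts must be non-negative (species ", sp, ")")
    }
    term <- h * f[[sp]]
    out <- if (is.null(out)) term else out + term
  }
  out
}

#' Relative stocking density
#'
#' The ratio of actual animal-unit density to carrying capacity,
#' `RSD = AU / CC`. A cell with zero capacity but positive stock gets `Inf`
#' (any stock on zero forage exceeds capacity and classifies as overstocked);
#' zero stock on zero capacity is nodata.
#'
#' @param au `raster_grid` of AU density (AU km-2).
#' @param cc `raster_grid` of carrying capacity (AU km-2 yr-1).
#' @export
rsd <- function(au, cc) {
  check_same_geometry(au, cc, "AU and CC")
  a <- grid_values(au); k <- grid_values(cc)
  r <- a / k
  r[which(k == 0 & a > 0)] <- Inf
  r[which(k == 0 & a == 0)] <- NA_real_
  grid_set_values(au, r)
}

#' Classify relative stocking density into pressure classes
#'
#' Integer-coded classification (1 = low pressure, 2 = medium pressure,
#' 3 = overstocked) with the class boundaries belonging to the medium class.
#' `Inf` ratios (stock on zero capacity) are overstocked.
#'
#' @param r `raster_grid` of RSD ratios.
#' @param scheme An [rsd_class_scheme()].
#' @return `raster_grid` of class codes, with the labels attached as the
#'   attribute `class_labels`.
#' @export
classify_rsd <- function(r, scheme = rsd_class_scheme()) {
  stopifnot(is_raster_grid(r))
  v <- grid_values(r)
  if (any(v < 0, na.rm = TRUE)) stop("RSD must be non-negative")
  cls <- ifelse(v < scheme$low_max, 1,
                ifelse(v <= scheme$med_max, 2, 3))
  out <- grid_set_values(r, cls)
  attr(out, "class_labels") <- scheme$labels
  out
}

annual_rsd_matrix <- function(au, cc_stack) {
  stopifnot(is_annual_stack(cc_stack))
  check_same_geometry(au, cc_stack$layers[[1]], "AU and CC stack")
  a <- as.vector(grid_values(au))
  k <- stack_matrix(cc_stack)
  r <- a / k
  r[which(k == 0 & a > 0)] <- Inf
  r[which(k == 0 & a == 0)] <- NA_real_
  r
}

#' Median relative stocking density over a window of years
#'
#' For each year of the window the annual RSD is formed against that year's
#' carrying capacity, then the per-pixel median of the annual ratios is
#' taken (the reference-period stocking-density map uses a five-year
#' window).
#'
#' @param au `raster_grid` of AU density.
#' @param cc_stack `annual_stack` of carrying capacity.
#' @param window_years Years of the window (must be in the stack); default
#'   all stack years.
#' @export
median_rsd_window <- function(au, cc_stack, window_years = NULL) {
  if (is.null(window_years)) window_years <- stack_years(cc_stack)
  if (length(window_years) == 0) stop("empty window")
  s <- stack_subset(cc_stack, window_years)
  r <- annual_rsd_matrix(au, s)
  med <- apply(r, 1, stats::median, na.rm = TRUE)
  med[!is.finite(med) & !is.infinite(med)] <- NA_real_
  grid_set_values(au, med)
}

#' Relative stocking density against the worst year
#'
#' RSD computed against the per-pixel minimum carrying capacity over all
#' stack years: how much stock each location can sustain in its least
#' productive year.
#'
#' @inheritParams median_rsd_window
#' @export
rsd_min_cc <- function(au, cc_stack) {
  k <- stack_matrix(cc_stack)
  kmin <- apply(k, 1, function(x) if (all(is.na(x))) NA_real_ else
    min(x, na.rm = TRUE))
  rsd(au, grid_set_values(au, kmin))
}

#' Fraction of years in the overstocked class
#'
#' Per pixel, the share of stack years in which the annual RSD exceeds the
#' overstocking boundary. Years with nodata capacity are excluded from the
#' denominator; pixels with no valid year are nodata.
#'
#' @inheritParams median_rsd_window
#' @param scheme An [rsd_class_scheme()].
#' @export
overstocked_year_fraction <- function(au, cc_stack,
                                      scheme = rsd_class_scheme()) {
  r <- annual_rsd_matrix(au, cc_stack)
  over <- r > scheme$med_max
  n_over <- rowSums(over, na.rm = TRUE)
  n_valid <- rowSums(!is.na(over))
  frac <- ifelse(n_valid == 0, NA_real_, n_over / n_valid)
  grid_set_values(au, frac)
}

#' Mask a grid or stack to the livestock-grazing extent
#'
#' Cells where the production-system mask is not `TRUE` become nodata;
#' values inside the mask are unchanged.
#'
#' @param x A `raster_grid` or `annual_stack`.
#' @param mask Boolean `raster_grid` (nonzero = keep).
#' @export
mask_livestock_grazing <- function(x, mask) {
  stopifnot(is_raster_grid(mask))
  apply_mask <- function(g) {
    check_same_geometry(g, mask, "data and mask")
    v <- grid_values(g)
    keep <- grid_values(mask)
    v[is.na(keep) | keep == 0] <- NA_real_
    grid_set_values(g, v)
  }
  if (is_annual_stack(x)) stack_map(x, apply_mask) else apply_mask(x)
}

#' Tabulate stocking-pressure class areas
#'
#' Counts and shares of valid cells per pressure class of a classified RSD
#' grid; the companion label/colour sidecar for categorical map exports.
#'
#' @param cls Classified grid from [classify_rsd()].
#' @param scheme An [rsd_class_scheme()].
#' @return Tibble with `code`, `label`, `n_cells`, `share`.
#' @export
rsd_class_table <- function(cls, scheme = rsd_class_scheme()) {
  v <- grid_values(cls)
  n <- vapply(1:3, function(k) sum(v == k, na.rm = TRUE), numeric(1))
  tibble::tibble(code = 1:3, label = scheme$labels, n_cells = n,
                 share = if (sum(n) > 0) n / sum(n) else rep(NA_real_, 3))
}
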