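#' Create a georeferenced raster grid
#'
#' The basic currency of the pipeline: a single-band 2-D layer on a regular,
#' axis-aligned, north-up grid with square cells. Row 1 is the northernmost
#' row (the convention of the ESRI ASCII grid format used for I/O). Missing
#' cells are stored as `NA` internally; `nodata` records the sentinel used
#' when the grid is written to or read from disk.
#'
#' @param values Numeric matrix (rows = north to south).
#' @param xll,yll Coordinates of the lower-left corner of the grid extent.
#' @param cellsize Cell edge length (map units); cells are square.
#' @param crs Coordinate reference system identifier (free-form string, e.g.
#'   an EPSG code or WKT). Grids only combine when their `crs` strings match.
#' @param nodata Sentinel value used on disk for missing cells.
#' @return An object of class `raster_grid`.
#' @examples
#' g <- raster_grid(matrix(1:6, 2, 3), crs = "EPSG:4326")
#' grid_values(g)
#' @export
raster_grid <- function(values, xll = 0, yll = 0, cellsize = 1,
                        crs = "local", nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(cellsize), length(cellsize) == 1, cellsize > 0)
  if (any(is.infinite(values), na.rm = TRUE)) {
    # infinities can arise legitimately (zero-capacity stocking ratios) and
    # are kept; NaN is coerced to NA
    values[is.nan(values)] <- NA_real_
  }
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize,
         crs = as.character(crs), nodata = nodata),
    class = "raster_grid"
  )
}

#' @export
is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Extract the value matrix of a grid
#' @param g A `raster_grid`.
#' @export
grid_values <- function(g) {
  stopifnot(is_raster_grid(g))
  g$values
}

#' Replace the values of a grid, keeping its geometry
#' @param g A `raster_grid`.
#' @param values Matrix or vector recyclable to the grid dimensions.
#' @export
grid_set_values <- function(g, values) {
  stopifnot(is_raster_grid(g))
  v <- matrix(as.numeric(values), nrow(g$values), ncol(g$values))
  v[is.nan(v)] <- NA_real_
  g$values <- v
  g
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

grid_extent <- function(g) {
  c(xmin = g$xll, xmax = g$xll + ncol(g$values) * g$cellsize,
    ymin = g$yll, ymax = g$yll + nrow(g$values) * g$cellsize)
}

#' Test whether two grids share geometry
#'
#' Same dimensions, origin, cell size (to a relative tolerance of 1e-9) and
#' CRS string.
#' @param a,b `raster_grid` objects.
#' @export
same_geometry <- function(a, b) {
  stopifnot(is_raster_grid(a), is_raster_grid(b))
  tol <- 1e-9 * max(a$cellsize, b$cellsize)
  all(dim(a$values) == dim(b$values)) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol && identical(a$crs, b$crs)
}

check_same_geometry <- function(a, b, what = "grids") {
  if (!same_geometry(a, b)) {
    stop("geometry mismatch between ", what,
         ": dimensions, origin, cell size and CRS must agree", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster_grid> %d x %d cells, cellsize %g, crs '%s'\n",
              d[1], d[2], x$cellsize, x$crs))
  cat(sprintf("  extent x [%g, %g], y [%g, %g]\n",
              x$xll, x$xll + d[2] * x$cellsize,
              x$yll, x$yll + d[1] * x$cellsize))
  if (length(v)) {
    cat(sprintf("  values: min %g, median %g, max %g (%d valid, %d nodata)\n",
                min(v), stats::median(v), max(v), length(v),
                sum(is.na(x$values))))
  } else {
    cat("  values: all nodata\n")
  }
  invisible(x)
}

#' Arithmetic on grids
#'
#' Element-wise arithmetic between grids (geometry-checked) or between a grid
#' and a scalar. Nodata cells propagate.
#' @param e1,e2 `raster_grid` or numeric scalar.
#' @export
Ops.raster_grid <- function(e1, e2) {
  if (nargs() == 1L) {
    return(grid_set_values(e1, get(.Generic)(grid_values(e1))))
  }
  if (is_raster_grid(e1) && is_raster_grid(e2)) {
    check_same_geometry(e1, e2, "operands")
    grid_set_values(e1, get(.Generic)(grid_values(e1), grid_values(e2)))
  } else if (is_raster_grid(e1)) {
    grid_set_values(e1, get(.Generic)(grid_values(e1), e2))
  } else {
    grid_set_values(e2, get(.Generic)(e1, grid_values(e2)))
  }
}

#' Apply a function to a grid's values
#' @param g A `raster_grid`.
#' @param f Vectorised function applied to the value matrix.
#' @param ... Passed on to `f`.
#' @export
grid_map <- function(g, f, ...) grid_set_values(g, f(grid_values(g), ...))

# ---------------------------------------------------------------------------
# Annual stacks

#' Create an annual stack
#'
#' An ordered sequence of grids on identical geometry, one per year; the
#' input to all temporal statistics.
#'
#' @param years Strictly increasing integer vector.
#' @param layers List of `raster_grid` objects, one per year.
#' @export
annual_stack <- function(years, layers) {
  years <- as.integer(years)
  stopifnot(length(years) == length(layers), length(years) >= 1)
  if (any(diff(years) <= 0)) stop("years must be strictly increasing")
  stopifnot(all(vapply(layers, is_raster_grid, logical(1))))
  for (i in seq_along(layers)[-1]) {
    check_same_geometry(layers[[1]], layers[[i]], "stack layers")
  }
  structure(list(years = years, layers = unname(layers)),
            class = "annual_stack")
}

#' @export
is_annual_stack <- function(x) inherits(x, "annual_stack")

#' @export
stack_years <- function(s) {
  stopifnot(is_annual_stack(s))
  s$years
}

#' Extract one layer of a stack
#' @param s An `annual_stack`.
#' @param year Calendar year (used if given).
#' @param index Positional index, used when `year` is missing.
#' @export
stack_layer <- function(s, year = NULL, index = NULL) {
  stopifnot(is_annual_stack(s))
  if (!is.null(year)) {
    index <- match(as.integer(year), s$years)
    if (is.na(index)) stop("year ", year, " not in stack")
  }
  stopifnot(!is.null(index))
  s$layers[[index]]
}

#' Subset a stack to a set of years
#' @param s An `annual_stack`.
#' @param years Years to keep (must all be present).
#' @export
stack_subset <- function(s, years) {
  idx <- match(as.integer(years), s$years)
  if (anyNA(idx)) stop("requested years not all present in stack")
  annual_stack(s$years[idx], s$layers[idx])
}

#' Flatten a stack into a pixels-by-years matrix
#'
#' Column j holds the values of year j, pixels in column-major matrix order.
#' @param s An `annual_stack`.
#' @export
stack_matrix <- function(s) {
  stopifnot(is_annual_stack(s))
  m <- vapply(s$layers, function(g) as.vector(grid_values(g)),
              numeric(length(grid_values(s$layers[[1]]))))
  matrix(m, ncol = length(s$years),
         dimnames = list(NULL, as.character(s$years)))
}

#' Build a stack from a pixels-by-years matrix on a template geometry
#' @param m Matrix with one column per year.
#' @param years Years, one per column of `m`.
#' @param template `raster_grid` supplying the geometry.
#' @export
matrix_stack <- function(m, years, template) {
  stopifnot(ncol(m) == length(years))
  annual_stack(years, lapply(seq_len(ncol(m)), function(j) {
    grid_set_values(template, m[, j])
  }))
}

#' Apply a function per layer of a stack
#' @param s An `annual_stack`.
#' @param f Function taking and returning a `raster_grid`.
#' @param ... Passed to `f`.
#' @export
stack_map <- function(s, f, ...) {
  annual_stack(s$years, lapply(s$layers, f, ...))
}

#' @export
print.annual_stack <- function(x, ...) {
  cat(sprintf("<annual_stack> %d years (%d-%d), %d x %d cells\n",
              length(x$years), min(x$years), max(x$years),
              nrow(x$layers[[1]]$values), ncol(x$layers[[1]]$values)))
  invisible(x)
}
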