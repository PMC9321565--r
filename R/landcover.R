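#' Modal land-cover class over years
#'
#' Per-pixel mode (the class occurring most often) of an annual stack of
#' integer-coded land-cover layers. Ties are broken deterministically by the
#' smallest class code. Pixels that are nodata in every year stay nodata.
#'
#' @param stack `annual_stack` of integer-coded (IGBP) class layers.
#' @return `raster_grid` of modal class codes.
#' @export
mode_landcover <- function(stack) {
  m <- stack_matrix(stack)
  if (any(m != round(m), na.rm = TRUE)) {
    stop("land-cover layers must be integer-coded")
  }
  # candidate codes sorted numerically, so which.max's first-hit rule
  # breaks ties toward the smallest code
  modes <- apply(m, 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    u <- sort(unique(x))
    cnt <- vapply(u, function(k) sum(x == k), numeric(1))
    u[which.max(cnt)]
  })
  grid_set_values(stack$layers[[1]], modes)
}

#' Grassland mask from a modal land-cover grid
#'
#' `TRUE` where the modal class belongs to the grass-bearing class set; the
#' IGBP default keeps woody savannas (8), savannas (9) and grasslands (10).
#'
#' @param mode_grid `raster_grid` of class codes, see [mode_landcover()].
#' @param class_set Integer class codes counted as grassland.
#' @return Boolean-valued `raster_grid` (1/0; nodata propagates).
#' @export
grassland_mask <- function(mode_grid, class_set = c(8, 9, 10)) {
  if (length(class_set) == 0) stop("empty grassland class set")
  v <- grid_values(mode_grid)
  grid_set_values(mode_grid, as.numeric(v %in% class_set & !is.na(v)) +
                    ifelse(is.na(v), NA_real_, 0))
}

#' Interpolate a sparse annual stack to a full set of years
#'
#' Per-pixel linear interpolation between anchor years, exact at the
#' anchors; target years outside the anchor range take the nearest anchor's
#' value (constant extension).
#'
#' @param sparse_stack `annual_stack` with the anchor years.
#' @param target_years Years of the interpolated output.
#' @export
interpolate_annual <- function(sparse_stack, target_years) {
  anchors <- stack_years(sparse_stack)
  if (length(anchors) == 0) stop("no anchor years")
  target_years <- as.integer(target_years)
  m <- stack_matrix(sparse_stack)
  out <- matrix(NA_real_, nrow(m), length(target_years))
  for (j in seq_along(target_years)) {
    ty <- target_years[j]
    if (length(anchors) == 1 || ty <= anchors[1]) {
      out[, j] <- m[, which.min(abs(anchors - ty))[1]]
      if (length(anchors) > 1 && ty <= anchors[1]) out[, j] <- m[, 1]
    } else if (ty >= anchors[length(anchors)]) {
      out[, j] <- m[, length(anchors)]
    } else {
      i0 <- max(which(anchors <= ty))
      i1 <- i0 + 1
      w <- (ty - anchors[i0]) / (anchors[i1] - anchors[i0])
      out[, j] <- (1 - w) * m[, i0] + w * m[, i1]
    }
  }
  matrix_stack(out, target_years, sparse_stack$layers[[1]])
}

# 1-D overlap weights between source and destination cell edges
overlap_weights <- function(src_start, src_n, dst_start, dst_n, src_cs, dst_cs) {
  src_edges <- src_start + (0:src_n) * src_cs
  dst_edges <- dst_start + (0:dst_n) * dst_cs
  w <- matrix(0, dst_n, src_n)
  for (i in seq_len(dst_n)) {
    lo <- dst_edges[i]; hi <- dst_edges[i + 1]
    ov <- pmin(hi, src_edges[-1]) - pmax(lo, src_edges[-(src_n + 1)])
    w[i, ] <- pmax(0, ov)
  }
  w
}

#' Resample a grid onto a reference geometry
#'
#' Harmonizes a layer to the geometry of a reference grid (in the pipeline,
#' everything is harmonized to the NPP geometry). Continuous layers use the
#' area-weighted mean of overlapping source cells, with nodata cells
#' excluded from the average; categorical layers take the value of the
#' source cell containing each destination cell centre (nearest-neighbour
#' for aligned grids; a centre on a cell edge resolves to the cell whose
#' interval starts at that edge). Both grids must be in the same CRS and
#' overlap.
#'
#' @param g `raster_grid` to resample.
#' @param reference `raster_grid` supplying the target geometry.
#' @param kind `"continuous"` or `"categorical"`.
#' @export
resample_to_reference <- function(g, reference,
                                  kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  stopifnot(is_raster_grid(g), is_raster_grid(reference))
  if (!identical(g$crs, reference$crs)) {
    stop("resampling requires matching CRS (no reprojection support)")
  }
  if (same_geometry(g, reference)) return(g)
  eg <- grid_extent(g); er <- grid_extent(reference)
  if (eg["xmax"] <= er["xmin"] || er["xmax"] <= eg["xmin"] ||
      eg["ymax"] <= er["ymin"] || er["ymax"] <= eg["ymin"]) {
    stop("grid and reference extents are disjoint")
  }
  nr_s <- nrow(g$values); nc_s <- ncol(g$values)
  nr_d <- nrow(reference$values); nc_d <- ncol(reference$values)
  if (kind == "continuous") {
    wx <- overlap_weights(g$xll, nc_s, reference$xll, nc_d,
                          g$cellsize, reference$cellsize)
    # rows run north->south: build weights on y using the top edge
    wy <- overlap_weights(-(g$yll + nr_s * g$cellsize), nr_s,
                          -(reference$yll + nr_d * reference$cellsize), nr_d,
                          g$cellsize, reference$cellsize)
    v <- g$values
    valid <- !is.na(v)
    v0 <- ifelse(valid, v, 0)
    num <- wy %*% v0 %*% t(wx)
    den <- wy %*% (valid + 0) %*% t(wx)
    out <- ifelse(den > 0, num / den, NA_real_)
  } else {
    xc <- reference$xll + (seq_len(nc_d) - 0.5) * reference$cellsize
    yc <- (reference$yll + nr_d * reference$cellsize) -
      (seq_len(nr_d) - 0.5) * reference$cellsize
    col_idx <- pmin(pmax(floor((xc - g$xll) / g$cellsize) + 1, 1), nc_s)
    ytop <- g$yll + nr_s * g$cellsize
    row_idx <- pmin(pmax(floor((ytop - yc) / g$cellsize) + 1, 1), nr_s)
    out <- g$values[row_idx, col_idx, drop = FALSE]
  }
  raster_grid(out, xll = reference$xll, yll = reference$yll,
              cellsize = reference$cellsize, crs = reference$crs,
              nodata = g$nodata)
}
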