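#' Tidy a grid into a cell-centre tibble
#'
#' One row per cell with map coordinates of the cell centre, the building
#' block of the plotting methods.
#'
#' @param x A [raster_grid()].
#' @param ... Unused.
#' @return Tibble with columns `x`, `y`, `value`.
#' @export
tidy.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  xc <- x$xll + (seq_len(d[2]) - 0.5) * x$cellsize
  yc <- (x$yll + d[1] * x$cellsize) - (seq_len(d[1]) - 0.5) * x$cellsize
  vals <- as.vector(x$values)
  tibble::tibble(
    x = rep(xc, each = d[1]),
    y = rep(yc, times = d[2]),
    value = vals
  )
}

#' Plot a grid as a filled map
#' @param object A [raster_grid()].
#' @param name Legend title.
#' @param ... Unused.
#' @export
autoplot.raster_grid <- function(object, name = "value", ...) {
  df <- tidy.raster_grid(object)
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = name, na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an annual stack as a year-faceted map panel
#' @param object An [annual_stack()].
#' @param name Legend title.
#' @param ... Unused.
#' @export
autoplot.annual_stack <- function(object, name = "value", ...) {
  df <- dplyr::bind_rows(lapply(seq_along(object$years), function(i) {
    dplyr::mutate(tidy.raster_grid(object$layers[[i]]),
                  year = object$years[i])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~year) +
    ggplot2::scale_fill_viridis_c(name = name, na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the significant scaled change of a trend map
#' @param object A `trend_map` from [pixel_trend()].
#' @param ... Unused.
#' @export
autoplot.trend_map <- function(object, ...) {
  df <- tidy.raster_grid(object$scaled_change)
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(
      name = sprintf("change per %d yr", object$n_years),
      low = "firebrick", mid = "white", high = "forestgreen",
      na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  subtitle = sprintf("significant at alpha = %g",
                                     object$alpha)) +
    ggplot2::theme_minimal()
}

#' Plot stocking-pressure classes
#' @param cls Classified grid from [classify_rsd()].
#' @param scheme The [rsd_class_scheme()] used.
#' @export
plot_rsd_classes <- function(cls, scheme = rsd_class_scheme()) {
  df <- tidy.raster_grid(cls)
  df$label <- factor(scheme$labels[df$value], levels = scheme$labels)
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, fill = label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      name = "stocking pressure", na.value = "grey90", drop = FALSE,
      values = c("low pressure" = "#2c7fb8", "medium pressure" = "#ffffb2",
                 "overstocked" = "#e31a1c")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
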