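#' Tidy a per-pixel trend map
#'
#' One row per pixel with valid trend statistics: coordinates, slope
#' (units per year), p value, significance flag and the scaled change over
#' the study window.
#'
#' @param x A `trend_map` from [pixel_trend()].
#' @param ... Unused.
#' @export
tidy.trend_map <- function(x, ...) {
  df <- tidy.raster_grid(x$slope)
  names(df)[names(df) == "value"] <- "slope"
  df$p_value <- as.vector(grid_values(x$p_value))
  df$significant <- as.vector(grid_values(x$significant)) == 1
  df$scaled_change <- as.vector(grid_values(x$scaled_change))
  df[!is.na(df$slope), ]
}

#' One-row summary of a trend map
#'
#' Counts of valid and significant pixels and the shares of significant
#' negative and positive trends.
#'
#' @param x A `trend_map`.
#' @param ... Unused.
#' @export
glance.trend_map <- function(x, ...) {
  sl <- as.vector(grid_values(x$slope))
  sig <- as.vector(grid_values(x$significant)) == 1
  valid <- !is.na(sl)
  tibble::tibble(
    n_pixels = sum(valid),
    n_significant = sum(sig & valid, na.rm = TRUE),
    share_negative = sum(sig & sl < 0, na.rm = TRUE) / max(sum(valid), 1),
    share_positive = sum(sig & sl > 0, na.rm = TRUE) / max(sum(valid), 1),
    alpha = x$alpha,
    n_years = x$n_years
  )
}

#' Tidy a Monte-Carlo ensemble summary
#'
#' Long tibble of per-pixel medians and CVs for each propagated variable.
#'
#' @param x An `mc_summary` from [propagate()].
#' @param ... Unused.
#' @export
tidy.mc_summary <- function(x, ...) {
  vars <- intersect(c("agb", "cc", "rsd"), names(x))
  dplyr::bind_rows(lapply(vars, function(v) {
    df <- tidy.raster_grid(x[[v]]$median)
    names(df)[names(df) == "value"] <- "median"
    df$cv <- as.vector(grid_values(x[[v]]$cv))
    df$variable <- v
    df
  }))
}

#' One-row summary of a Monte-Carlo ensemble
#' @param x An `mc_summary`.
#' @param ... Unused.
#' @export
glance.mc_summary <- function(x, ...) {
  vars <- intersect(c("agb", "cc", "rsd"), names(x))
  dplyr::bind_rows(lapply(vars, function(v) {
    cv <- grid_values(x[[v]]$cv)
    tibble::tibble(variable = v,
                   median_cv = stats::median(cv[is.finite(cv)]),
                   n_draws = x$n_draws)
  }))
}
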