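#' Per-pixel linear trend of an annual stack
#'
#' Ordinary least squares of cell value against the 0-based year index, so
#' the slope is the change per year. Significance is the two-sided t test of
#' the slope; `scaled_change` is `slope * n_years` (the change over the full
#' study window) masked to significant pixels. Pixels with fewer than 3
#' valid years are nodata. A perfectly constant series has slope 0 and is
#' reported as not significant.
#'
#' @param stack An [annual_stack()].
#' @param alpha Significance level for the mask (default 0.05).
#' @return Object of class `trend_map` with `raster_grid` fields `slope`,
#'   `p_value`, `significant` and `scaled_change`, plus `alpha` and
#'   `n_years`.
#' @export
pixel_trend <- function(stack, alpha = 0.05) {
  y <- stack_matrix(stack)
  t_full <- stack_years(stack) - stack_years(stack)[1]
  valid <- !is.na(y)
  n <- rowSums(valid)
  tm <- matrix(rep(t_full, each = nrow(y)), nrow(y))
  tm[!valid] <- NA
  y0 <- y; y0[!valid] <- 0
  t0 <- tm; t0[!valid] <- 0
  tbar <- rowSums(t0) / n
  ybar <- rowSums(y0) / n
  dt <- (t0 - tbar); dt[!valid] <- 0
  dy <- (y0 - ybar); dy[!valid] <- 0
  sxx <- rowSums(dt^2)
  sxy <- rowSums(dt * dy)
  slope <- sxy / sxx
  fit <- sweep(dt, 1, slope, "*")
  res <- dy - fit
  res[!valid] <- 0
  rss <- rowSums(res^2)
  df <- n - 2
  se <- sqrt(rss / pmax(df, 1) / sxx)
  tstat <- slope / se
  p <- 2 * stats::pt(-abs(tstat), df = pmax(df, 1))
  p[which(se == 0 & slope == 0)] <- 1      # constant series
  p[which(se == 0 & slope != 0)] <- 0      # exact non-constant line
  bad <- n < 3 | sxx == 0
  slope[bad] <- NA_real_
  p[bad] <- NA_real_
  template <- stack$layers[[1]]
  sig <- as.numeric(p < alpha)
  scaled <- slope * length(stack_years(stack))
  scaled[which(is.na(sig) | sig == 0)] <- NA_real_
  structure(list(
    slope = grid_set_values(template, slope),
    p_value = grid_set_values(template, p),
    significant = grid_set_values(template, sig),
    scaled_change = grid_set_values(template, scaled),
    alpha = alpha,
    n_years = length(stack_years(stack))
  ), class = "trend_map")
}

#' @export
print.trend_map <- function(x, ...) {
  p <- grid_values(x$p_value)
  cat(sprintf(
    "<trend_map> %d years, alpha = %g: %d / %d valid pixels significant\n",
    x$n_years, x$alpha, sum(grid_values(x$significant) == 1, na.rm = TRUE),
    sum(!is.na(p))))
  invisible(x)
}

#' Kendall rank trend of an annual series
#'
#' Kendall rank correlation of a series against its time index (tau-b, so
#' tied values are corrected for), with the two-sided p value from
#' [stats::cor.test()]. An all-equal series has no defined trend and returns
#' `NA`.
#'
#' @param series Numeric vector (length >= 4; `NA`s dropped).
#' @param time Optional time index (defaults to the observation order).
#' @return List with `tau` and `p`.
#' @export
kendall_trend <- function(series, time = seq_along(series)) {
  keep <- !is.na(series)
  series <- series[keep]; time <- time[keep]
  if (length(series) < 4) stop("Kendall trend needs at least 4 observations")
  if (length(unique(series)) == 1) return(list(tau = NA_real_, p = NA_real_))
  ct <- suppressWarnings(
    stats::cor.test(time, series, method = "kendall", exact = FALSE))
  list(tau = unname(ct$estimate), p = unname(ct$p.value))
}

significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.01, "***",
                ifelse(p < 0.05, "**",
                       ifelse(p < 0.10, "*", ""))))
}

#' Interannual coefficient of variation
#'
#' Per-pixel `100 * sd / mean` across years (sample sd); nodata where the
#' temporal mean is not positive or fewer than 2 valid years exist.
#'
#' @param stack An [annual_stack()].
#' @export
interannual_cv <- function(stack) {
  m <- stack_matrix(stack)
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  s <- apply(m, 1, stats::sd, na.rm = TRUE)
  cv <- 100 * s / mu
  cv[which(mu <= 0 | n < 2)] <- NA_real_
  grid_set_values(stack$layers[[1]], cv)
}

#' Minimum-to-median ratio across years
#'
#' Per-pixel minimum annual value divided by the median annual value, a
#' `[0, 1]` measure of how far the worst year falls below typical
#' conditions. Nodata where the median is not positive.
#'
#' @param stack An [annual_stack()].
#' @export
min_median_ratio <- function(stack) {
  m <- stack_matrix(stack)
  mn <- apply(m, 1, function(x) if (all(is.na(x))) NA_real_ else
    min(x, na.rm = TRUE))
  md <- apply(m, 1, stats::median, na.rm = TRUE)
  r <- mn / md
  r[which(md <= 0)] <- NA_real_
  grid_set_values(stack$layers[[1]], r)
}

#' Zonal statistics of a grid or stack
#'
#' Aggregates values over an integer-coded zone raster, per year for a
#' stack: `sum`, `mean` or `median` over valid cells, or `area` (total cell
#' area, in squared map units, of valid cells). Zones with no valid overlap
#' are dropped.
#'
#' @param x A `raster_grid` or `annual_stack`.
#' @param zones Integer-coded `raster_grid` on the same geometry.
#' @param statistic One of `"sum"`, `"mean"`, `"median"`, `"area"`.
#' @return Tibble with columns `zone`, `year` (NA for a single grid),
#'   `statistic`, `value`, of class `zonal_result`.
#' @export
zonal_summary <- function(x, zones,
                          statistic = c("sum", "mean", "median", "area")) {
  statistic <- match.arg(statistic)
  stopifnot(is_raster_grid(zones))
  if (is_raster_grid(x)) x <- annual_stack(1L, list(x))
  check_same_geometry(x$layers[[1]], zones, "data and zones")
  z <- as.vector(grid_values(zones))
  cell_area <- zones$cellsize^2
  m <- stack_matrix(x)
  rows <- list()
  for (zk in sort(unique(z[!is.na(z)]))) {
    in_zone <- which(z == zk)
    for (j in seq_along(x$years)) {
      v <- m[in_zone, j]
      v <- v[!is.na(v)]
      if (!length(v)) next
      val <- switch(statistic,
                    sum = sum(v), mean = mean(v),
                    median = stats::median(v),
                    area = length(v) * cell_area)
      rows[[length(rows) + 1]] <-
        tibble::tibble(zone = zk, year = x$years[j],
                       statistic = statistic, value = val)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("zonal_result", class(out))
  out
}

#' Kendall trend per zone of a zonal table
#'
#' Applies [kendall_trend()] to each zone's annual series and attaches
#' significance stars at the 10% (`*`), 5% (`**`) and 1% (`***`) levels.
#'
#' @param zonal Tibble from [zonal_summary()] on a stack.
#' @return Tibble with `zone`, `statistic`, `tau`, `p`, `stars`.
#' @export
zonal_trend <- function(zonal) {
  stopifnot(all(c("zone", "year", "value") %in% names(zonal)))
  zonal |>
    dplyr::group_by(.data$zone, .data$statistic) |>
    dplyr::summarise(
      res = list(kendall_trend(.data$value[order(.data$year)])),
      .groups = "drop") |>
    dplyr::mutate(tau = purrr::map_dbl(.data$res, "tau"),
                  p = purrr::map_dbl(.data$res, "p"),
                  stars = significance_stars(.data$p)) |>
    dplyr::select(-"res")
}
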