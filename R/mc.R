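#' Specification of one uncertain scalar parameter
#'
#' Distribution of a single uncertain parameter used in forward uncertainty
#' propagation. Two kinds are supported:
#'
#' * `"truncated_normal"`: bounded on `[lower, upper]`. If `mean` is given it
#'   is the mean of the *truncated* distribution, and the location parameter
#'   is calibrated accordingly; otherwise the interval midpoint is used
#'   (symmetric truncation, so the truncated mean equals the midpoint). If
#'   `sd` is missing the underlying scale defaults to `(upper - lower) / 4`
#'   (about 95% of untruncated mass inside the bounds) unless the mean is
#'   off-centre, in which case the distance to the nearer bound divided by 2
#'   is used, so the bounds sit at least two scale units from the mean.
#' * `"uniform"`: either bounds directly, or `(mean, sd)` converted to
#'   `mean +/- sqrt(3) * sd`.
#'
#' @param name Parameter name.
#' @param kind `"truncated_normal"` or `"uniform"`.
#' @param lower,upper Bounds (required for truncated normal).
#' @param mean,sd Optional moments, interpreted as described above.
#' @export
param_spec <- function(name, kind = c("truncated_normal", "uniform"),
                       lower = NULL, upper = NULL, mean = NULL, sd = NULL) {
  kind <- match.arg(kind)
  if (kind == "uniform") {
    if (is.null(lower) || is.null(upper)) {
      if (is.null(mean) || is.null(sd)) {
        stop("uniform spec needs bounds or (mean, sd)")
      }
      lower <- mean - sqrt(3) * sd
      upper <- mean + sqrt(3) * sd
    }
  } else {
    if (is.null(lower) || is.null(upper)) {
      stop("truncated normal spec needs bounds")
    }
    if (is.null(mean)) mean <- (lower + upper) / 2
    if (is.null(sd)) {
      half <- min(mean - lower, upper - mean)
      sd <- if (abs(mean - (lower + upper) / 2) < 1e-12 * (upper - lower)) {
        (upper - lower) / 4
      } else {
        half / 2
      }
    }
  }
  # equal bounds describe a degenerate (known-exactly) parameter
  if (lower > upper) stop("spec bounds must satisfy lower <= upper")
  if (!is.null(mean) && (mean < lower || mean > upper)) {
    stop("spec mean lies outside its bounds")
  }
  structure(list(name = name, kind = kind, lower = lower, upper = upper,
                 mean = mean, sd = sd), class = "param_spec")
}

# location parameter such that the [lower, upper]-truncated normal with
# scale `sd` has the requested mean
truncnorm_location <- function(target_mean, sd, lower, upper) {
  if (sd <= 0) return(target_mean)
  tmean <- function(mu) {
    a <- (lower - mu) / sd; b <- (upper - mu) / sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    if (z < 1e-300) return(if (mu < lower) lower else upper)
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  }
  half <- upper - lower
  stats::uniroot(function(mu) tmean(mu) - target_mean,
                 lower = lower - 20 * sd - half,
                 upper = upper + 20 * sd + half,
                 tol = 1e-12)$root
}

#' Moments of a parameter specification
#'
#' Mean and standard deviation of the distribution a [param_spec()]
#' describes (for a truncated normal, the moments of the truncated
#' distribution), computed from the standard closed forms. Useful as a
#' delta-method building block.
#'
#' @param spec A [param_spec()].
#' @return Named vector `c(mean, sd)`.
#' @export
spec_moments <- function(spec) {
  if (spec$lower == spec$upper) {
    c(mean = spec$lower, sd = 0)
  } else if (spec$kind == "uniform") {
    c(mean = (spec$lower + spec$upper) / 2,
      sd = (spec$upper - spec$lower) / sqrt(12))
  } else {
    mu <- truncnorm_location(spec$mean, spec$sd, spec$lower, spec$upper)
    a <- (spec$lower - mu) / spec$sd; b <- (spec$upper - mu) / spec$sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    m <- mu + spec$sd * (stats::dnorm(a) - stats::dnorm(b)) / z
    v <- spec$sd^2 * (1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / z -
                        ((stats::dnorm(a) - stats::dnorm(b)) / z)^2)
    c(mean = m, sd = sqrt(v))
  }
}

#' Draw samples of one uncertain parameter
#'
#' Inverse-CDF sampling: uniforms are rescaled to the bounds; truncated
#' normals use `qnorm` restricted to the probability mass inside the bounds,
#' so every draw lies in `[lower, upper]` by construction.
#'
#' @param spec A [param_spec()].
#' @param n Number of draws.
#' @param seed Optional seed for an independent reproducible stream.
#' @export
sample_parameter <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "param_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  if (spec$lower == spec$upper) {
    rep(spec$lower, n)
  } else if (spec$kind == "uniform") {
    spec$lower + u * (spec$upper - spec$lower)
  } else {
    mu <- truncnorm_location(spec$mean, spec$sd, spec$lower, spec$upper)
    p_lo <- stats::pnorm(spec$lower, mu, spec$sd)
    p_hi <- stats::pnorm(spec$upper, mu, spec$sd)
    x <- stats::qnorm(p_lo + u * (p_hi - p_lo), mu, spec$sd)
    pmin(pmax(x, spec$lower), spec$upper)
  }
}

#' Default uncertainty specifications
#'
#' The full parameter set of the forward uncertainty analysis: multiplicative
#' uniform factors on NPP (sd 0.07) and on the aboveground allocation
#' fraction (sd 0.198 * 0.71 = 0.14058), truncated-normal carbon conversion
#' factor on `[0.47, 0.50]`, truncated-normal daily intake fraction on
#' `[0.018, 0.04]` with mean 0.02, and truncated-normal animal-unit
#' conversion factors per species (see [au_factor_table()]; the cattle row
#' has stated mean 1.00 and scale 0.125 so its upper bound sits two scale
#' units above the mean).
#'
#' @return Named list of [param_spec()] objects (`npp`, `fanpp`, `carbon`,
#'   `intake`, and `au_<species>`).
#' @export
default_param_specs <- function() {
  factors <- au_factor_table()
  au_specs <- lapply(seq_len(nrow(factors)), function(i) {
    mean_i <- if (factors$species[i] == "cattle") 1.00 else NULL
    sd_i <- if (factors$species[i] == "cattle") 0.125 else NULL
    param_spec(paste0("au_", factors$species[i]), "truncated_normal",
               lower = factors$lower[i], upper = factors$upper[i],
               mean = mean_i, sd = sd_i)
  })
  names(au_specs) <- paste0("au_", factors$species)
  c(list(
    npp = param_spec("npp", "uniform", mean = 1, sd = 0.07),
    fanpp = param_spec("fanpp", "uniform", mean = 1, sd = 0.198 * 0.71),
    carbon = param_spec("carbon", "truncated_normal",
                        lower = 0.47, upper = 0.50),
    intake = param_spec("intake", "truncated_normal",
                        lower = 0.018, upper = 0.04, mean = 0.02)
  ), au_specs)
}

#' Coefficient of variation over ensemble draws
#'
#' Per-pixel `100 * sd / mean` over Monte-Carlo draws (sample sd, `n - 1`
#' denominator); nodata where the mean is zero.
#'
#' @param draws Matrix, pixels in rows and draws in columns (at least 2).
#' @return Numeric vector of CV percentages.
#' @export
ensemble_cv <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) stop("CV needs at least 2 draws")
  m <- rowMeans(draws)
  s <- sqrt(rowSums((draws - m)^2) / (ncol(draws) - 1))
  cv <- 100 * s / m
  cv[which(m == 0)] <- NA_real_
  cv
}

row_median <- function(m) apply(m, 1, stats::median)

#' Propagate parameter uncertainty through the AGB-CC-RSD chain
#'
#' Forward Monte Carlo: each draw samples one global scalar per uncertain
#' parameter (the uncertain quantities are conversion factors and global
#' calibrations, so a draw perturbs the whole map coherently) and reruns the
#' deterministic chain: AGB from NPP with the sampled NPP and allocation
#' factors and carbon fraction, CC with the sampled intake, the animal-unit
#' map with the sampled species factors, and RSD as their ratio draw by
#' draw. Summaries are the per-pixel median and CV over draws.
#'
#' @param inputs List with elements `npp` (a `raster_grid` for the year
#'   being propagated), `mat`, `canopy`, `slope`, and optionally `heads`
#'   (named list of headcount grids; needed for the RSD ensemble) and `mask`
#'   (applied to all outputs).
#' @param specs Named list of [param_spec()] objects as in
#'   [default_param_specs()].
#' @param n Number of draws (>= 1).
#' @param seed RNG seed; all parameter streams derive from it.
#' @param params Point [agb_params()] supplying the non-sampled coefficients.
#' @return List of class `mc_summary` with elements `agb`, `cc` and (if
#'   headcounts are given) `rsd`, each holding `median` and `cv` grids, plus
#'   `n_draws`.
#' @export
propagate <- function(inputs, specs = default_param_specs(), n = 1000,
                      seed = 1, params = agb_params()) {
  if (n < 1) stop("n must be >= 1")
  stopifnot(is_raster_grid(inputs$npp))
  set.seed(seed)
  draws <- lapply(specs, sample_parameter, n = n)

  f <- fanpp(inputs$mat, params)
  tree <- tree_cover_multiplier(inputs$canopy, params)
  smult <- slope_multiplier(inputs$slope, params$slope_table)
  # deterministic per-pixel part of AGB, before the sampled global factors
  agb_det <- grid_values(inputs$npp * f * tree * smult)
  if (!is.null(inputs$mask)) {
    agb_det <- grid_values(mask_livestock_grazing(
      grid_set_values(inputs$npp, agb_det), inputs$mask))
  }
  v <- as.vector(agb_det)

  k_agb <- draws$npp * draws$fanpp / draws$carbon     # length n
  agb_draws <- outer(v, k_agb)                        # pixels x draws
  cc_draws <- sweep(agb_draws * 1000, 2,
                    455 * draws$intake * 365, "/")

  template <- inputs$npp
  summarize <- function(m) {
    list(median = grid_set_values(template, row_median(m)),
         cv = grid_set_values(template, if (n >= 2) ensemble_cv(m) else
           rep(NA_real_, nrow(m))))
  }
  out <- list(agb = summarize(agb_draws), cc = summarize(cc_draws),
              n_draws = n)

  if (!is.null(inputs$heads)) {
    au_draws <- 0
    for (sp in names(inputs$heads)) {
      h <- as.vector(grid_values(inputs$heads[[sp]]))
      au_draws <- au_draws + outer(h, draws[[paste0("au_", sp)]])
    }
    r <- au_draws / cc_draws
    r[which(cc_draws == 0 & au_draws > 0)] <- Inf
    r[which(cc_draws == 0 & au_draws == 0)] <- NA_real_
    out$rsd <- summarize(r)
  }
  structure(out, class = "mc_summary")
}
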