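# grasscc

Estimate how many grazing animals the world's grasslands can feed — and
where current stocking exceeds that capacity — from gridded annual net
primary productivity.

`grasscc` is an R package for rangeland scientists and food-system
modellers. It implements, on any axis-aligned raster grid, the full chain
from NPP to livestock carrying capacity and relative stocking density:

1. **Aboveground allocation** — the fraction of NPP allocated aboveground
   is modelled linearly in mean annual temperature,
   `f_ANPP = 0.171 + 0.0129·MAT`; cells where the fraction is non-positive
   (MAT below about −13 °C) are excluded.
2. **Aboveground biomass (AGB, g m⁻² yr⁻¹)** —
   `AGB = NPP·f_ANPP / c · exp(−4.45521·x) · s(slope)`, with carbon
   fraction `c` (0.475), canopy cover `x`, and a slope-class step function
   `s` (≤10 % → 1.0, ≤30 % → 0.7, ≤60 % → 0.4, >60 % → 0).
3. **Carrying capacity (CC, AU km⁻² yr⁻¹)** —
   `CC = AGB / (455 · intake · 365)` for a 455 kg animal unit with daily
   intake fraction 0.02 (range 0.018–0.04).
4. **Relative stocking density (RSD)** — species headcounts (cattle,
   buffalo, sheep, goats, horses) are converted to animal units and
   divided by CC, then classified with proper-use-factor boundaries:
   < 0.20 low pressure, 0.20–0.65 medium pressure, > 0.65 overstocked.

Around that core the package provides Monte-Carlo propagation of the
parameter uncertainties (truncated-normal and uniform specifications,
median and CV maps over 1000 draws), per-pixel OLS trends with
significance masking, Kendall rank trends for zonal annual series,
interannual-variability statistics, land-cover mode compositing and
grassland masking, grid harmonization, and a synthetic-scenario generator
with planted ground truth so the whole pipeline is testable without any
external satellite or census data. Rasters are exchanged as plain-text
ESRI ASCII grids (with `.prj` CRS sidecars); tabular results are tibbles
with `tidy()`/`glance()`/`autoplot()` support.

## Worked example

A complete run on a synthetic 32 × 32 scenario (15 years, 1000 draws):

```r
library(grasscc)

cfg <- run_config(scenario = scenario_config(rows = 32, cols = 32, seed = 42),
                  n_draws = 1000, rng_seed = 7)
run <- run_pipeline(cfg)
#> simulate: 32 x 32 cells, 15 years
#> grassland mask: 717 / 1024 cells retained
#> AGB: 717 cells defined (cold/nodata exclusions: 0)
#> RSD: 717 cells in display mask, 542 in grazing systems
#> Monte Carlo: 1000 draws x 5 window years

run
#> <cc_run> 15 years, 1000 MC draws, window 2006-2010
#> # A tibble: 3 × 4
#>    code label           n_cells share
#>   <int> <chr>             <dbl> <dbl>
#> 1     1 low pressure        368 0.513
#> 2     2 medium pressure     182 0.254
#> 3     3 overstocked         167 0.233
```

51 % of the masked grassland sits below a stocking ratio of 0.20 (stock
well within capacity), 25 % between 0.20 and 0.65, and 23 % above 0.65 —
i.e. demanding more forage than the land supplies without supplementary
feed. The trend summary:

```r
glance(run$trend)
#> # A tibble: 1 × 6
#>   n_pixels n_significant share_negative share_positive alpha n_years
#>      <int>         <int>          <dbl>          <dbl> <dbl>   <int>
#> 1      717           185          0.146          0.112  0.05      15
```

14.6 % of grassland pixels show a significant (α = 0.05) decline in
carrying capacity over the 15 years and 11.2 % a significant increase.
Zonal Kendall trends come starred at the 10/5/1 % levels:

```r
run$zonal_trend
#> # A tibble: 4 × 5
#>    zone statistic    tau         p stars
#>   <dbl> <chr>      <dbl>     <dbl> <chr>
#> 1     1 sum       -0.276 0.151     ""
#> 2     2 sum        0.752 0.0000925 "***"
#> 3     3 sum       -0.467 0.0153    "**"
#> 4     4 sum        0.371 0.0536    "*"
```

Parameter uncertainty, as the median pixel-level CV over the Monte-Carlo
ensemble, is 15.7 % for AGB, 16.4 % for CC and 18.2 % for RSD in this run
— the stocking ratio inherits extra spread from the animal-unit
conversion factors. `autoplot(run$rsd_median)`,
`plot_rsd_classes(run$rsd_classes)` and `autoplot(run$trend)` draw the
maps; `run$manifest` lists every product, and setting `out_dir` in the
config writes them all (rasters, CSV tables, manifest) to disk. A thin
command-line front end lives at `inst/cli/grasscc.R`
(`simulate`, `pipeline` subcommands).

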