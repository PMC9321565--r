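---
title: "Modelling grassland carrying capacity and relative stocking density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling grassland carrying capacity and relative stocking density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grasscc)
```

## The model

Grassland carrying capacity (CC) asks how many grazing animals a piece of
land can feed from its own primary production. `grasscc` implements a
raster pipeline that answers this per pixel from four gridded drivers —
annual net primary productivity (NPP, g C m⁻² yr⁻¹), mean annual
temperature (MAT, °C), tree-canopy cover fraction, and terrain slope (%) —
plus categorical land cover, species-resolved livestock headcounts, and a
livestock-production-system mask.

The chain has four steps.

**1. Aboveground allocation.** Plants store part of their production below
ground. The aboveground fraction is modelled linearly in temperature,

$$f_{\mathrm{ANPP}} = 0.171 + 0.0129\,\mathrm{MAT},$$

an empirical grassland relationship. The fraction reaches zero at
MAT ≈ −13.26 °C; we exclude (set to nodata) every cell where
$f_{\mathrm{ANPP}} \le 0$ at the *exact* root of the linear form rather
than at a rounded integer temperature — the equation, not its rounding,
defines the mask.

**2. Aboveground biomass (AGB).** NPP in carbon units is converted to dry
biomass by dividing by the biomass carbon fraction (point value 0.475, the
conventional biomass carbon content), then restricted by two
accessibility multipliers:

$$\mathrm{AGB} = \frac{\mathrm{NPP} \cdot f_{\mathrm{ANPP}}}{c}
  \cdot e^{-4.45521\,x} \cdot s(\mathrm{slope}),$$

where $x$ is canopy cover and $e^{-4.45521 x}$ is a transfer function for
the sub-canopy forage available to grazers, fitted to published
canopy-vs-understory scatter data; it equals 1 in the open and ≈ 0.012
under a closed canopy. $s(\cdot)$ is a step function over terrain slope
classes — the default table is (≤ 10 % → 1.0, ≤ 30 % → 0.7, ≤ 60 % → 0.4,
> 60 % → 0.0), a standard grazing-suitability reclassification; published
recommendations give the scheme qualitatively rather than as a fixed
table, so the breakpoints are fully configurable and a class boundary
belongs to the gentler class.

**3. Carrying capacity.** An animal unit (AU) is a 455 kg grazer eating a
daily dry-matter fraction of its body weight (0.018–0.04; point value
0.02). With AGB converted to kg km⁻² yr⁻¹,

$$\mathrm{CC} = \frac{\mathrm{AGB}}{455 \cdot \mathrm{intake} \cdot 365}
  \quad [\mathrm{AU\,km^{-2}\,yr^{-1}}].$$

**4. Relative stocking density (RSD).** Species headcounts (cattle,
buffalo, sheep, goats, horses) are converted to AU densities with
per-species factors and divided by CC. RSD is classified with the minimum
(0.20) and maximum (0.65) proper-use factors from the rangeland
literature: < 0.20 low pressure, 0.20–0.65 medium pressure, > 0.65
overstocked. Because grasslands vary between years, the headline RSD map
uses the per-pixel *median* of annual ratios over a five-year reference
window; a pessimistic variant uses the per-pixel *minimum* CC over all
years, and a third product reports the share of years each pixel would be
overstocked.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `fanpp_intercept`, `fanpp_slope` | 0.171, 0.0129 | –, °C⁻¹ | empirical grassland allocation model |
| `tree_decay` | 4.45521 | – | canopy transfer-function fit |
| `carbon_factor` | 0.475 | g C / g | conventional biomass carbon fraction, inside the uncertainty interval [0.47, 0.50] |
| slope table | 10/30/60 % → 1/0.7/0.4/0 | % | grazing-suitability reclassification |
| `au_weight` | 455 | kg | animal-unit definition |
| `daily_intake_fraction` | 0.02 | – | point intake within [0.018, 0.04] |
| class thresholds | 0.20 / 0.65 | – | min/max proper-use factors |
| `agb_floor` | 0.1 | g m⁻² yr⁻¹ | display mask on output maps |
| `n_draws` | 1000 | – | Monte-Carlo ensemble size |

Every entry is overridable programmatically or through the declarative
YAML run configuration (`read_run_config()`), because these parameters
*are* the experiment.

## Uncertainty propagation

The forward Monte Carlo perturbs the uncertain scalars: uniform
multiplicative factors on NPP (sd 0.07) and on $f_{\mathrm{ANPP}}$
(sd 0.198 × 0.71 = 0.14058, converted to bounds mean ± √3·sd), and
truncated normals for the carbon fraction [0.47, 0.50], the intake
fraction [0.018, 0.04] (mean 0.02), and the per-species AU conversion
factors. Design choices worth stating explicitly:

* **Stated means are means of the truncated distribution.** For the intake
  row the stated mean (0.02) sits close to the lower bound; reading it as
  the location parameter of the underlying normal would make draws average
  ≈ 0.023. We instead calibrate the location so the *truncated* mean equals
  the stated value, which keeps long-run draw averages on the printed
  numbers. Rows without a stated mean use the interval midpoint, where both
  readings coincide exactly.
* **Scale choices.** Rows with bounds only use sd = range/4 (≈ 95 % of
  untruncated mass inside the bounds). The cattle row (bounds 0.50–1.25,
  mean 1.00) uses sd = 0.125 so the upper bound sits two scale units above
  the mean; other off-centre means use half the distance to the nearer
  bound.
* **One scalar per draw, applied globally.** The uncertain quantities are
  conversion factors and global calibrations, not spatially independent
  fields; drawing them per pixel would average the uncertainty away at map
  level.
* **RSD draw-by-draw.** The RSD ensemble divides each draw's AU map by the
  same draw's CC map, so correlated numerator/denominator uncertainty is
  preserved.
* Sample statistics use the *n* − 1 denominator; the per-pixel summary is
  the median and the coefficient of variation CV = 100·sd/mean over draws.
* The canopy transfer function's own confidence band (available only as
  quantile curves of an external fit, not as a parametric spread) is not
  propagated; only its point curve is used. This will understate
  uncertainty in densely wooded cells.

For the default specifications the chain is (nearly) a product of
independent factors, so the delta method predicts
$\mathrm{CV}^2(\mathrm{CC}) \approx \sum_i \mathrm{CV}^2_i$; the test suite
verifies the propagated ensemble against this closed-form prediction at
*n* = 1000 within 15 % relative tolerance.

## Temporal statistics

Per-pixel trends are ordinary least squares of value on the 0-based year
index; the change map multiplies the slope by the number of study years
and is masked to two-sided *t*-test significance at α = 0.05 (the default;
the level is configurable since presentation-grade maps often leave it
unstated). No multiple-testing correction is applied across pixels — the
map is a per-pixel presentation, and readers should treat marginal
significance accordingly. Regional and zonal annual series get the Kendall
rank trend (tau-b, so ties are corrected) with stars at the 10/5/1 %
levels. Interannual variability is the CV across years; the
minimum-to-median ratio summarises how far the worst year falls below
typical conditions. A constant series is reported as slope 0, not
significant, rather than nodata.

## The synthetic generator

Real inputs for this analysis are global satellite and census products.
The package ships a generator that emulates their *statistical structure*
at desk scale so the whole chain is testable end to end:

$$\mathrm{NPP}(x, y, t) = \mathrm{base}(x, y)\,
  \bigl(1 + \beta(x, y)\,t\bigr)\,\varepsilon_t,
  \qquad \varepsilon_t \sim \mathrm{lognormal}(0, \sigma^2)\ \text{i.i.d.}$$

* The base field is lognormal around 250 g C m⁻² yr⁻¹ (a typical grassland
  value) with spatial CV 0.3; multiplicative lognormal noise keeps NPP
  positive and right-skewed and matches CV-style interannual variability
  (default σ = 0.1, within the 10–40 % range seen on real grasslands).
* Spatial autocorrelation comes from separable moving-average smoothing of
  white noise — the simplest controllable mechanism.
* The trend field β (default sd 0.01 yr⁻¹) is planted per pixel, so trend
  recovery can be checked exactly (σ = 0) and statistically (σ > 0).
* The IGBP mosaic assigns *exactly* the configured grassland fraction
  (default 0.7) across woody savannas/savannas/grasslands (codes 8/9/10),
  with a small rate of spurious annual class flips capped so the modal
  class always recovers the assignment.
* MAT has a south-to-north gradient around 10 °C and is held constant over
  years; per-year MAT would only rescale the allocation fraction year-wise
  without exercising any additional contract.
* Headcounts are built backwards from stratified target stocking ratios
  (about 40/30/30 % low/medium/overstocked, drawn clear of the 0.20/0.65
  boundaries) against the reference-year CC, then split across species by
  gamma-field weights — so classification can be compared against
  construction, not against the code under test.

What the generator does **not** emulate: real geographic pattern, sensor
artifacts, spatially correlated interannual anomalies (droughts hit
neighbouring pixels together in reality), per-year temperature, or any
feedback of grazing onto NPP. Passing tests therefore demonstrate
correctness of the computational contracts, not skill against real-world
data.

## Numerical and I/O choices

* Rasters are exchanged as ESRI ASCII grids with a `.prj` CRS sidecar, and
  annual stacks as per-year files with a CSV manifest — plain-text,
  self-describing formats readable by any GIS stack. Grids are square-cell,
  axis-aligned and north-up; reprojection between CRSs is out of scope.
* Harmonization resamples everything to the NPP geometry: area-weighted
  means for continuous layers (nodata excluded from averages),
  containing-cell lookup for categorical ones. The canopy transfer
  function should be applied at native resolution *before* averaging when
  preparing real data, because the function is non-linear.
* Land-cover mode ties break toward the smallest class code —
  deterministic and documented.
* RSD at zero capacity: CC = 0 with stock present is treated as infinite
  pressure (overstocked), not nodata — any stock on zero forage exceeds
  capacity; CC = 0 with zero stock is undefined (nodata).
* Class boundaries 0.20 and 0.65 classify as medium pressure (the interval
  is read as closed); configurable.
* Truncated-normal sampling is inverse-CDF via `qnorm` restricted to the
  in-bounds probability mass, so draws respect bounds by construction.

## Problem sizes

The test suite runs scenarios of 16 × 16 up to 64 × 64 cells over 15
years, 1000 Monte-Carlo draws for the dispersion checks, and a 40 × 40
grid (≥ 1000 grassland pixels) for statistical trend recovery — sizes
chosen so every contract is exercised with comfortable statistical power
while the whole suite stays interactive. The pipeline itself is linear in
cells × years × draws and has been run at 64 × 64 × 15 × 1000 without
strain.

## Known limitations

Beyond the generator caveats above: forage *quality* is not modelled
(C4-dominated tropical grass is less digestible than its biomass
suggests); supplementary feeding, seasonal CC and migratory herds are out
of scope, so RSD > 1 does not necessarily mean degradation where feed is
imported; and headline global figures require the real satellite/census
input stack — desk-scale synthetic runs exercise the method, not the
world.
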