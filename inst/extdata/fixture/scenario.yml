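rows: 16.0
cols: 16.0
years:
- 2001
- 2002
- 2003
- 2004
- 2005
- 2006
- 2007
- 2008
- 2009
- 2010
- 2011
- 2012
- 2013
- 2014
- 2015
seed: 2.0
npp_mean: 250.0
npp_spatial_cv: 0.3
smoothness: 3.0
beta_mean: 0.0
beta_sd: 0.01
sigma: 0.1
mat_mean: 10.0
mat_gradient: 10.0
mat_noise_sd: 1.0
canopy_mean: 0.15
canopy_sd: 0.15
slope_mean: 8.0
slope_sd: 10.0
grassland_fraction: 0.7
grass_classes:
- 8.0
- 9.0
- 10.0
filler_classes:
- 7.0
- 12.0
- 13.0
- 16.0
lc_flip_rate: 0.03
class_fractions:
- 0.4
- 0.3
- 0.3
rsd_target_ranges:
  low:
  - 0.02
  - 0.17
  medium:
  - 0.25
  - 0.6
  overstocked:
  - 0.7
  - 1.5
grazing_fraction: 0.7
background_au: 2.0
zones_dim:
- 2.0
- 2.0
cellsize: 1.0
crs: local-km
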