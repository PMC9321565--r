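ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
      1       1       0       1       0       1       1       1       1       1       1       1       1       1       1       1
      0       0       0       0       0       1       1       1       1       1       1       1       1       1       1       1
      1       0       0       0       1       1       1       1       1       1       1       1       1       1       1       1
      1       1       0       0       0       0       1       1       1       1       1       1       1       1       1       1
      1       0       0       0       1       1       1       1       1       1       1       1       1       1       1       1
      0       0       0       0       0       1       1       1       1       1       1       1       1       1       1       1
      0       0       0       0       0       1       1       1       1       1       1       1       1       1       1       1
      1       1       0       0       1       1       1       1       1       1       1       1       1       1       1       1
      1       1       0       1       1       1       1       1       1       1       1       1       1       1       0       0
      1       1       1       1       1       1       1       1       1       1       1       1       0       0       0       0
      1       0       1       1       1       1       1       1       1       0       0       1       0       0       0       0
      1       1       1       1       1       0       0       0       0       0       0       1       0       0       0       1
      1       1       1       1       1       1       1       1       1       0       0       0       0       0       0       0
      1       1       1       1       1       1       1       1       1       0       0       0       0       0       0       0
      1       1       1       1       1       1       1       1       1       1       0       0       0       0       0       0
      1       1       1       1       1       1       1       1       1       1       1       0       0       0       0       0
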