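ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
      9      10      16       7      12      13      12      13       7      16      13       7      12      12      10      10
      8       9      10      16      13      12      12      12      12       7      13      12      10       9       9       9
      8      10      10       7      12      12      16      13      12      13      10      12       7      12      12      13
      9       7      16      12       7      16      13      10       9       9       8       9      10      10      10       9
      8      12      10      12       7      12      12      10       9       9       9       8      10      10      10       9
      9      12      10      13      12      16      12      16      10      10      16       9       9       9       9       8
      9      10       9       7       7       7       7      16      10      10      10      10      10       9       9       8
      8       8       8       9      16      10      16      12      13      13      12      13      13      10       9       8
      8       9       8      13      13      10      10      10       9      10      10      10      10      10       9      13
      9       9       8       9      10       9      10      16      10      10      12      13      10       8       9       8
      9       8       8       8       9       9       9       9       9       9      13      10       8       8       8       9
     10      10       8      10      10      10       9       9       9       8      10       9       8       8       8       9
     16       9       8      12      10      10       9       8       8       8       8       9      16       8       8      10
     10       9       8       9       9       9       8       8       8       8       9       9       7       8       9      16
     13      10       9      10       9       9       8       8       8       8       8       9       8       8       8      10
      7      13      12      13      10      12      10      10       9       8       8       8       8       8       8      10
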