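ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
323.382 274.722  237.66 218.077 350.001 389.045 263.976 273.224 169.198     257 371.917 373.649 310.801 336.613  256.31 307.984
331.493 289.944 250.422 191.349 285.466 317.275 252.491 264.377 156.634 215.434 358.657 178.895 263.264  330.88 252.594 354.743
374.535 262.842 245.673 354.636 392.905 339.389 309.831 293.011  216.99 263.649 415.241 403.576 368.952 407.798 321.509  372.93
270.328 270.249 235.607 244.507 323.709 342.533 260.846 243.256 203.483  258.25 302.039 295.606 217.404  302.72 313.925 417.184
263.878  222.06  184.14 223.705 232.441 304.111 244.011 238.454 238.889  320.99 295.842 273.449 191.442 228.152 268.941 318.608
245.237 207.383 206.983  236.22 255.694 219.179 213.953 164.975 177.374 224.857  262.42 209.974 188.987 222.416 184.673 251.777
301.465 275.738 268.679 283.329 322.811 259.845 240.379 180.083 178.081 208.918 229.293 155.105 161.068 177.773 202.626 211.808
227.768 231.285 201.217 226.353 280.176 217.487 223.758 187.428 270.441 267.523 231.634 207.259 198.275 184.295 192.215 158.751
222.392 212.411 208.954  242.97 212.016 210.024 244.083 175.647 238.424 252.326 219.672  261.09 205.106 208.302 209.601 189.782
208.277 253.594 244.006 247.236 173.788 192.974 226.382 166.339 224.071 228.772 167.643 183.183 161.954 133.844 162.564 149.953
171.355 159.129 164.293 165.638 140.517 180.507 186.558  173.92 223.912 270.589 176.108 225.313 201.495 145.177 159.424 111.314
167.889 190.784 222.711 230.583 174.531 160.229 216.888 157.441 167.909 198.344   170.6 218.261 223.392 149.415 225.098 133.111
177.815 148.974 214.969 224.086 198.533 188.106 326.083 221.531 275.453 283.659 219.727 414.039 289.127 251.433 273.109 202.273
123.991 135.251 193.896 178.593 156.171 152.418 228.271  211.96  335.31 319.852 376.631  519.95 419.863 375.931 355.498 211.534
172.298 158.076  215.24 173.871 165.617 185.591 271.315  253.57 256.417 375.966 430.509 536.896 478.478 466.302 603.494  308.96
156.904 143.475 175.559  181.19 214.532 184.267 264.093 276.996 334.956 394.216 549.703 667.463 601.461 439.945 413.925 247.729
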