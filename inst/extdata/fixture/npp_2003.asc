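ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
230.224 292.396 216.323 235.647 267.042 316.645 255.103 205.994 214.266 201.048 345.363 321.213 258.201 369.408 299.787 337.255
309.916  256.27 249.799 226.322 291.336 311.624 270.297 184.204 179.641  223.02 292.924  288.23 192.908 313.779 258.566 335.443
324.668 346.274 270.075 323.437  259.75 368.023  267.37 208.108 182.363 296.631 393.052 382.786 316.691 413.348 308.436 424.777
279.046 272.706 219.885 250.023 286.244 358.457 275.009 217.615 207.296 219.601 296.992 241.028 291.202 317.414 288.187 396.859
300.108 226.354 184.499 237.948 313.746 357.396  223.52 260.288 214.072 261.485 281.495 228.557 184.922 274.545 313.252 330.576
277.947 220.098  177.88 196.057 279.785 290.362 189.558 173.362 233.335 234.665 255.101 230.666 156.178 221.222  193.08 233.212
382.216 345.618 289.492 346.385 262.654 243.517 236.877 193.068 234.268 228.183 195.327 195.823 163.988 211.914 219.973 244.072
294.064 227.429 227.601 253.291 201.373 269.305 227.724 214.915 238.212 247.667 243.742 175.691 218.402 174.635 158.445 191.348
244.285 199.852  223.68 271.662 203.195 203.549 243.184 198.562 249.841 254.127 183.089 263.696 194.334 189.113 170.535 202.933
205.115 171.263 254.757 219.529 224.645 189.024 183.326  157.65 207.153 209.276 147.957 172.289 132.357 145.847 161.865 162.009
188.044 198.729 157.514 198.254  142.59 179.447 191.791 181.163 187.031  225.15 199.791 272.599 194.493  158.17 160.277 135.877
178.259 191.506 193.052 178.355 176.674 195.135 222.736 193.859 190.819 218.368 174.651 205.716 196.839 142.524  180.75 124.622
179.358 178.143 239.343 179.349  229.27 195.898 295.352 240.222 219.991 334.755 253.804  378.59 320.449 252.876 254.241 183.077
147.576 146.299 200.353 163.713 190.642 143.658 230.804 232.509 307.325 351.196 395.907 505.587 423.483 367.761 439.382 252.921
187.597  151.98 189.389 171.568 174.888 158.684 235.045 229.549 308.578 468.501 422.391 710.162 527.042 469.197 422.158 208.993
149.212  149.09 171.342 166.999 225.492 191.584 278.751 290.714 349.645 531.342 641.492  769.53 463.173 450.239 504.578 214.921
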