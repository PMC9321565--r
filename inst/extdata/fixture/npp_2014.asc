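ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
241.426   210.1 215.191 175.902 211.845 242.174   264.9 206.127 179.337 205.112  251.23 334.314 304.816 372.637 278.773  317.35
292.261 259.967 221.658 210.685 247.557 247.623 202.176 189.133 185.357 217.328 260.878 277.525  232.12 328.481 303.198 351.829
339.799 304.691 272.744 263.054  261.66 317.021 248.699 201.328 209.181 341.705  383.69 352.878 327.978 514.897 377.598  378.08
306.829 279.036 222.234 207.031 262.565 286.118 231.978 171.719 179.532 244.857  264.39 233.296 243.599 357.783 357.097 446.085
311.388 255.061 186.346 195.936 291.865 335.368 248.581 183.197 244.858 178.791 317.426 209.829 177.406 301.413 233.482 419.736
321.781 239.451  199.75 183.492 231.727 247.862 168.946 154.776 175.883 200.596 242.619 189.042 137.521 219.747 197.235 214.623
 387.19 331.031 347.435 279.068 279.206 273.596 211.939 175.614 165.934 201.063 191.802 130.345 109.487  175.96  190.61 166.293
373.638 279.353 240.301 291.476 230.023 234.294 227.931 189.449 232.591 238.052  205.02 154.714 134.086 153.166 170.021 186.783
279.007 232.245 222.755  203.88 242.182  253.38 197.299 193.857 232.485 225.407 193.192 179.856 155.558 152.062 169.157 153.807
206.291 230.142 203.197 211.353 214.893 223.921 220.761 147.116 185.973 171.599 144.833 164.223 129.688 149.611 191.484 134.424
170.248 140.407 155.341 213.976 140.202 187.217 175.237 205.072 241.363 284.649 198.506 238.754 174.883 163.382  181.38 146.239
185.406  196.31 214.769 201.464 184.656 213.714 277.511 209.399 240.594 235.067   211.2 264.767 187.307 188.496 215.944 111.045
136.911 212.106  240.13 189.951 224.081 339.169 337.591 291.127  332.39  479.44 276.653 399.883 311.303 213.802  294.98 178.401
147.375 153.554 172.503 209.575 171.051 146.573 220.201 269.313 356.414 423.696 423.391 661.101 475.738 512.279 460.852 218.239
 188.08 212.462 196.284 189.578 196.218  171.74 220.211 211.428  318.81 481.045 558.679 717.484 756.236  509.12 596.994 311.826
219.301  197.62 185.645 191.712 201.587 214.039 283.287 399.889 504.917 566.036 625.136 763.709 704.714 541.514 522.855 314.688
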