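ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
209.954 317.884 234.556 229.052 269.157 323.168 278.677 198.941 178.679 235.416 358.632 301.425  259.84 348.872 261.217 287.913
287.473 276.463 233.101 246.867 265.073 307.848  222.31  181.71  187.74 239.501 296.781  266.41 185.929 273.456 311.508 312.627
313.088  269.24 286.665  370.25 338.935 335.288 268.118 203.373 233.499 329.475 347.829 351.931 356.826 456.901 317.167 452.145
 283.69 274.498 251.571  210.81 366.036 330.759 223.608 242.742 147.672 263.158 347.765 269.753 253.567 361.525 300.341 374.609
305.398 270.402 234.506 241.492 258.691 301.161 202.282 220.636 220.253 300.274 289.493 232.052   164.2 296.462 257.337 280.304
343.595  259.47 178.665 194.689 188.541 242.015 161.709  138.94 191.342 194.989 241.298 158.372 158.814 208.723  207.79   216.6
396.436 333.818 290.911 268.494 254.636 346.619 185.513  191.43 217.376 237.897 175.073 159.485 143.863  196.72 169.431 227.014
291.205  256.39 209.881 262.086 283.324 222.896 209.778 214.026 266.804 257.266 237.075 193.508 191.563 162.708 184.261 166.156
317.008 190.652  232.09 265.601 200.646 226.113 200.856 187.363  272.61 243.609 192.138 253.802 156.519 161.014 186.485 215.101
197.146 210.216 205.682 206.032 206.204 228.182 183.175 164.095 185.464 195.066 175.937 206.302 133.878  137.25 176.883 168.525
197.664 173.319 224.085 206.878 161.533 165.742 210.484 187.827 229.659 228.541 222.212 264.341 211.631 188.612 183.469  125.38
184.344 242.555  253.73 199.519 193.115 177.156  235.79 170.612 202.464 223.555 225.124 239.109 224.292 163.655 209.271 125.462
174.411 219.329 199.882 200.359 249.617 229.883 322.221 320.025 333.249 415.835 276.751 389.356 322.138 194.167 263.045 180.947
170.016 169.046 179.303 174.777 166.372 157.472  239.84 180.096 342.801 358.267 374.629 511.033  392.85  413.49 286.972 227.531
235.162 159.339 176.929 171.251 156.715 150.805 245.287 226.818 312.563 437.545  458.31 724.705 608.038 555.397 555.374 291.024
192.684 180.184   150.4 166.624 206.905 190.819 279.982 321.253 324.232 502.533 639.916 592.499 645.308 413.298 494.963 223.911
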