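ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
 224.11 259.827 222.353 203.378  273.04 307.027 278.958   224.5 179.076 187.798 354.181  388.64  241.74 374.018 266.745 317.121
277.762 285.001 223.251 252.075 256.152 257.499 183.264  225.68 155.968 179.075 240.253 284.833 259.778 269.153 303.019  332.34
371.721  305.59 235.197  296.82 302.347 300.773 277.673 211.862 200.691  286.67 368.978 388.166 331.447 499.994 353.779 464.734
305.595 247.487 222.108  226.31 331.091 251.454 252.201 145.604 185.711 281.911 306.992 250.713 226.594 339.367 339.647 375.727
303.889 285.213 187.436 181.749 249.721 324.215 223.654 237.569 202.595 223.783 297.338 203.013 159.758  302.25 227.412 370.941
338.219 250.552  219.52  215.29 197.492 234.297 161.642 141.417 184.558 161.632 186.734 162.457 130.699 179.798 182.558 195.314
404.707 308.851 339.547 363.854 258.064 301.821 202.662   169.2 166.335 157.139 153.068  168.38 114.253 154.712 181.453 206.607
301.504 241.548 257.789 219.196 244.146 311.632 184.305 230.903 226.395 226.481  265.49  173.95 145.754 192.338 153.284 169.573
342.757 250.617 240.154  221.94 221.429  250.54 227.336  188.88 238.906 264.085 190.881 173.337 205.376 173.392 162.463 181.477
226.674 203.752 272.476  252.24 215.592 212.533 220.578 184.385 176.187 187.684 147.219 150.096 115.073 140.738 146.334 135.378
170.459  171.98 167.988 175.019 182.534 177.024 191.379 185.053 251.776 235.832 178.034 213.537 191.003 165.941  151.16 110.095
191.981 199.483 213.967 223.809 187.989 228.541 258.571 225.877 181.578 256.995 168.384 250.461 185.154 162.202 182.354 124.817
160.205 184.555   200.6 252.304 245.824 287.348 314.285 293.327 352.739 353.549 375.922  348.09 311.832 265.522 301.925 181.335
150.031 175.241 215.564  142.33 166.549 130.752 259.108 230.691 369.641 399.524 428.845 693.323 487.906 403.195 428.077 265.568
 152.61 173.114  185.23 192.951 157.085 165.738 196.855 253.385 350.519 427.943 438.872 806.091 628.024 498.648 663.721  257.72
212.873  166.54 149.317 162.427 206.339 180.645 287.829 365.506 341.623 618.645 681.811 686.071 631.659 519.078 539.844 351.263
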