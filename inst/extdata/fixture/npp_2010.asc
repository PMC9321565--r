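ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
 206.26 261.811 227.038 201.263 229.342 305.722 263.475  226.94 162.738 176.878 281.995 320.489 254.839 396.051 275.209 311.251
299.282 250.477 231.301 245.167 262.998 294.364 218.528 160.224 178.117 190.857 254.525 293.134 249.429 255.411 289.365 345.291
351.146 285.163 260.505  353.81 327.453 281.808 222.886 202.422 188.653 242.246 439.554 427.331 295.495 453.423 317.627 387.531
230.484 274.752 198.822 220.066 274.984 327.219 212.597 166.078 161.256  230.65 362.616 281.101 190.895 325.587 364.866 425.203
315.994 224.227 178.303 206.778  249.01 351.148 238.592 180.748 211.411  319.72 306.327 218.991   184.8 255.961 252.657 432.657
273.192  195.31 196.416 223.291 239.808 227.536 176.669  137.23 188.463 205.201 240.359 228.483 147.822 197.621 195.378 246.844
406.326 350.864 238.489 371.385 307.873 303.577 222.198 181.337 178.023 189.088 191.611 132.763  134.28 147.348 184.996 223.737
343.401 227.483 210.585  239.17 242.074 259.927 165.358 226.528 249.914 261.243 220.789 177.143 156.819 153.973 172.626 182.409
313.281 232.578  188.08 247.124 203.375 176.586 195.744 174.609 242.082  252.73 179.887 218.528  234.81 178.008 159.757 175.965
217.797 241.144 233.144 230.009 248.593 233.462 210.166 149.365 220.197  185.33 149.999 157.717  141.36 152.155 160.537 154.767
191.583 184.659 145.992  182.93 154.163 189.877 203.156 194.278 270.219 272.469 181.633 227.832 158.928  172.03 180.273 106.058
215.691 198.189 201.048 257.837 190.169 200.608 255.639 198.771 181.597 223.926 163.443  220.32 201.847 129.974 247.074 139.296
205.244 162.106 254.977 208.264 257.101 259.021 299.719 299.951 321.351 356.185 349.651 365.509 279.738 252.328 327.967  172.68
139.105 130.383 174.187 145.317 184.982 146.338 287.262 246.213 317.427 357.522 419.999 828.664 475.834 438.256 427.733 242.952
172.549 158.755 169.356 150.976 153.137 156.369 283.268 273.971 294.382 479.126 437.424 713.401 708.339 556.353  508.24     307
179.576 194.195 190.316 158.476 199.029 173.345 268.338 329.845  455.57 695.483 600.532 776.187 623.345  450.38 552.274 292.978
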