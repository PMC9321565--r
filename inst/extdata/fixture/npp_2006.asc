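ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
 221.83 315.751 214.838 225.838 280.091 331.293 223.884 210.428 213.733 278.032 340.952 290.646 291.778 368.521 315.111 328.981
236.199 324.548 244.731 242.452 290.457  319.27 195.062  230.61 170.708 191.136 299.965 320.273 238.498 301.582 278.417 336.404
381.171 290.451 237.582 294.213 305.405 327.713  259.82 193.755 231.514 306.501 395.785 355.658  341.56 350.513 295.764 548.469
282.076 262.881  219.72  198.71 326.449 342.683 256.444 210.499 159.593 238.131 308.612 260.619 231.602 349.633 327.351 427.303
317.085 266.709 184.412 201.606 290.753 334.497 242.707 220.376 199.045 254.941 323.848  255.29 188.258  267.34 239.863 300.911
300.935 246.602 221.932  187.37 224.352 253.378 178.426 182.144 183.183 218.469 274.591 225.248 157.411 224.422  176.72 196.511
317.934 322.773 336.674 343.784 253.708 253.071 211.923  175.61 193.434 212.508 219.082 189.522   137.4 196.337 206.041 175.375
238.366 231.676 284.415 284.629 240.722 233.754 190.948 211.382 249.634  226.89 256.717 239.209 169.117 182.611 147.725 192.291
273.809 213.975  256.62 304.932  234.85 221.975 252.421 201.295 272.088 227.266 220.126 247.295 162.161 211.483 199.858 173.326
184.067 218.374 234.182 206.862 197.206  224.22 179.662 164.376 143.642 202.612 163.471  186.76  138.77 137.619 171.878 175.226
 160.03 143.473 160.171 208.303 140.866 204.358 199.627 187.813 205.634 266.659 165.899 220.316 242.697 155.144 144.959 117.302
175.565 172.182 255.716 186.913 247.362 161.407 258.777  171.12 171.572 219.968 197.297 275.923 180.542 152.171 215.781  149.17
  195.4 196.878 235.079  198.23 196.777 246.129 327.983  305.48 312.367 301.597 256.154 383.089 348.935 200.935 300.423 165.361
160.413  160.64 199.647 163.375 177.719 132.262 257.401 212.856 337.036 373.329 387.896 554.983 356.919   304.1 390.716  208.43
217.032 161.124  161.35 162.507 173.485 147.727 207.218 248.053 304.801 356.863 491.652 620.228 535.539 452.011 519.356 303.957
157.874 170.875 194.862 198.436 232.291 169.205 302.068 344.547 344.542 585.787 546.181 785.512 686.408 452.231 405.159 249.107
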