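ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 1
NODATA_value -9999
234.635 273.038 209.739 186.003  272.22 299.438 218.776 194.908 175.351 216.324 304.208 260.309 258.907 385.179 221.649 242.098
 283.92 260.825 241.446 207.737 251.808 250.768 194.943 170.222 164.599  220.19 269.357 255.008 275.603 328.014 274.683 302.122
306.734  307.16 297.536 315.901   291.9 273.588 235.669 212.209 186.978  225.67 382.678 382.867 297.447  445.27 356.207 431.945
230.274 307.341 227.946 257.106  290.42 325.506 216.098 161.639 177.057 268.898 312.972  256.86 228.591  327.98 289.672 443.321
337.488 241.519 214.653 232.742 218.177 297.823 230.855 229.795 169.546 265.336 276.566 209.171 202.364  283.43 220.413 343.802
267.393 250.388  191.79 207.359 199.731 246.108 162.359 134.056 160.671 176.791 238.807 198.258 171.113 216.994 180.015 241.663
437.758 349.522 288.992 319.607  277.75 314.799 178.698  168.38 180.243 226.326 188.078 152.436 111.957 152.921  184.73 196.645
246.169 247.371 251.435 244.893 249.943 248.104 212.786 226.473 253.994 232.347 230.667 159.764 153.087 186.904 189.253 134.012
363.065 186.912  213.15  229.37 224.299 214.556 228.625   182.1 217.773 221.518 155.671 158.565 155.938 180.187 163.121 180.498
231.519 210.442 235.437 221.145 172.061 198.804  176.67 144.281  175.78 203.263 154.695 199.292 128.593 113.484 182.656 154.103
186.107 160.362 176.231 173.582 141.009 189.498 237.358 212.062 200.459 293.195 193.864 238.164 212.888 140.324 157.846 99.5841
174.355 226.667  208.63 259.573 199.454 189.181 279.915  192.49 199.877 221.852 178.117 267.982 229.471 132.075 216.776 140.302
153.407 202.009 203.075 216.303 259.776 291.117 329.406 278.942 417.318 366.458 279.015 394.104   287.7 244.986 363.069 164.665
124.202 124.519 181.685 152.119 188.757 137.673 224.721 282.254 314.049 424.358 476.609 680.382 447.223 351.742 484.468 204.779
202.542 164.854 177.975 185.157 158.618 153.002 241.079 190.785 303.961 457.826 490.557 766.413 621.431 446.432 600.714 279.552
  178.9 150.487 194.123 205.854 196.344 163.776 264.609 318.031 426.727 562.634 679.244 804.803 628.051 515.107   478.7  249.46
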